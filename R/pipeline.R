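# End-to-end pipeline: simulate -> train -> predict -> evaluate.

#' Pipeline run configuration
#'
#' Assembles the configuration of a full reproducible run. Precedence when
#' loaded from YAML with overrides: explicit arguments > file > defaults.
#'
#' @param out_dir Output directory for all artifacts.
#' @param n_exams Number of simulated examinations.
#' @param grid Phantom grid shape.
#' @param noise_sd Phantom voxel noise SD (HU).
#' @param edge_case_fraction Fraction of decision-boundary edge cases.
#' @param strategy `"two_step"`, `"one_step"`, or `"both"`.
#' @param model_preset [net_config()] preset name.
#' @param train_preset [train_config()] preset name.
#' @param epochs Override of the preset epoch count.
#' @param calibrate Apply phase-order calibration to exam-level labels.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = "ctphase-run", n_exams = 40L,
                       grid = c(32L, 32L, 32L), noise_sd = 5,
                       edge_case_fraction = 0, strategy = "two_step",
                       model_preset = "desk", train_preset = "desk",
                       epochs = NULL, calibrate = TRUE, seed = 1L) {
  structure(
    list(out_dir = out_dir, n_exams = as.integer(n_exams),
         grid = as.integer(grid), noise_sd = noise_sd,
         edge_case_fraction = edge_case_fraction, strategy = strategy,
         model_preset = model_preset, train_preset = train_preset,
         epochs = epochs, calibrate = isTRUE(calibrate),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @param ... Overrides taking precedence over the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' Run the full pipeline
#'
#' Simulates a labelled phantom cohort, trains the models the chosen
#' strategy needs (3-class + 2-class for two-step, 4-class for one-step),
#' predicts on a held-out simulated test cohort, and writes volumes,
#' manifests, checkpoints, a predictions CSV, and a metrics report (CSV +
#' JSON) under `config$out_dir`. Every artifact embeds the seed; a rerun
#' with the same configuration reproduces the run.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "train", "predict", "evaluate")`
#'   to execute; earlier artifacts must exist for later stages.
#' @return Invisibly, a list with the trained models, prediction tibble and
#'   metrics report (for the stages run).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "train", "predict", "evaluate")) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  spec <- phantom_spec(grid = config$grid)
  profile <- enhancement_profile(noise_sd = config$noise_sd)
  phase_sets <- list(c("arterial", "PVP", "DP"))
  train_dir <- file.path(out, "train")
  test_dir <- file.path(out, "test")
  res <- list()

  if ("simulate" %in% stages) {
    train_exams <- simulate_cohort(config$n_exams, spec, profile,
                                   seed = derive_seed(config$seed, "train_cohort"),
                                   edge_case_fraction = config$edge_case_fraction,
                                   phase_sets = phase_sets)
    test_exams <- simulate_cohort(max(8L, config$n_exams %/% 3L), spec, profile,
                                  seed = derive_seed(config$seed, "test_cohort"),
                                  edge_case_fraction = config$edge_case_fraction,
                                  phase_sets = phase_sets)
    write_cohort(train_exams, train_dir)
    write_cohort(test_exams, test_dir)
  }

  models_needed <- switch(config$strategy,
                          two_step = c(3L, 2L), one_step = 4L,
                          both = c(3L, 2L, 4L))
  ckpt <- function(k) file.path(out, sprintf("model%d.rds", k))

  if ("train" %in% stages) {
    assert_that(file.exists(file.path(train_dir, "manifest.csv")),
                "no simulated training cohort found: run the simulate stage first")
    train_exams <- load_exams(file.path(train_dir, "manifest.csv"))
    for (k in models_needed) {
      ncf <- net_config(config$model_preset, n_classes = k)
      tcf <- train_config(config$train_preset,
                          epochs = config$epochs,
                          seed = derive_seed(config$seed, paste0("train", k)))
      model <- train_model(train_exams, ncf, tcf)
      save_checkpoint(model, ckpt(k))
      res[[paste0("model", k)]] <- model
    }
  }

  if ("predict" %in% stages) {
    assert_that(all(file.exists(map_chr(models_needed, ckpt))),
                "missing model checkpoint: run the train stage first")
    assert_that(file.exists(file.path(test_dir, "manifest.csv")),
                "no simulated test cohort found: run the simulate stage first")
    test_exams <- load_exams(file.path(test_dir, "manifest.csv"))
    preds <- list()
    for (ex in test_exams) {
      if (config$strategy %in% c("two_step", "both")) {
        preds[[length(preds) + 1L]] <- predict_two_step(
          ex, load_checkpoint(ckpt(3L)), load_checkpoint(ckpt(2L)),
          calibrate = config$calibrate)
      }
      if (config$strategy %in% c("one_step", "both")) {
        preds[[length(preds) + 1L]] <- predict_one_step(
          ex, load_checkpoint(ckpt(4L)), calibrate = config$calibrate)
      }
    }
    pred_tbl <- bind_predictions(preds)
    pred_tbl$seed <- config$seed
    write_predictions(pred_tbl, file.path(out, "predictions.csv"))
    res$predictions <- pred_tbl
  }

  if ("evaluate" %in% stages) {
    ppath <- file.path(out, "predictions.csv")
    assert_that(file.exists(ppath),
                "no predictions found: run the predict stage first")
    pred_tbl <- as_tibble(read.csv(ppath, stringsAsFactors = FALSE))
    reports <- map(split(pred_tbl, pred_tbl$strategy), function(p) {
      counts <- confusion_from_predictions(p$label_raw, p$true_phase)
      metrics_from_counts(counts, digits = c(1, 3))
    })
    for (st in names(reports)) {
      write.csv(as_tibble(reports[[st]]),
                file.path(out, sprintf("metrics_%s.csv", st)), row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = config$seed,
           overall_accuracy = map(reports, function(r) attr(r, "overall_accuracy"))),
      file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
    res$metrics <- reports
  }
  invisible(res)
}
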