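# One-step and two-step (cascaded) prediction strategies and phase-order
# calibration.

# Obtain per-phase probability rows for an exam from a trained model, or from
# a plain function (used to exercise the cascade contract independently of
# training). Models preprocess raw-HU exams to their input grid on the fly.
exam_probs <- function(model, exam) {
  if (is.function(model)) {
    probs <- model(exam)
  } else {
    assert_that(inherits(model, "phase_model"), "model must be a phase_model or function")
    ex <- maybe_preprocess(exam, model)
    probs <- forward_exam(ex, model$net)
  }
  assert_that(is.matrix(probs) && nrow(probs) == length(exam$phases),
              "model must return one probability row per phase")
  assert_that(all(abs(rowSums(probs) - 1) <= 1e-6),
              "probability rows must sum to 1")
  probs
}

maybe_preprocess <- function(exam, model) {
  shp <- model$net$config$input_shape
  needs <- any(map_lgl(exam$phases, function(p) {
    !identical(dim(p$values), shp) || min(p$values) < 0 || max(p$values) > 1
  }))
  if (needs) {
    preprocess_exam(exam, shp, model$window[["level"]], model$window[["width"]])
  } else exam
}

new_exam_prediction <- function(tbl, strategy, step2_invocations = NA_integer_) {
  structure(tbl, class = c("exam_prediction", class(tbl)),
            strategy = strategy, step2_invocations = step2_invocations)
}

#' One-step (direct 4-class) prediction
#'
#' Classifies every phase of the exam directly into EAP/LAP/PVP/DP from a
#' single forward pass of the 4-class model. Ties break to the first class in
#' canonical order (EAP, LAP, PVP, DP).
#'
#' @param exam An [examination()].
#' @param model4 A 4-class `phase_model` (or a function returning a
#'   phases x 4 probability matrix).
#' @param calibrate Apply [calibrate_order()] to the exam-level labels.
#' @return An `exam_prediction` tibble: one row per phase with the 4-class
#'   probabilities, raw and calibrated labels, relative order and strategy.
#' @export
predict_one_step <- function(exam, model4, calibrate = TRUE) {
  assert_that(length(exam$phases) >= 1, "empty examination")
  probs <- exam_probs(model4, exam)
  assert_that(ncol(probs) == 4, "one-step prediction needs a 4-class model")
  colnames(probs) <- PHASES4
  labels <- PHASES4[apply(probs, 1, which.max)]
  out <- assemble_prediction(exam, probs, labels, "one_step")
  if (calibrate) out <- calibrate_order(out, exam$order_known) else out
}

#' Compose a 4-class probability vector from cascade outputs
#'
#' Product rule over the cascade: `(p_AP * p_EAP, p_AP * p_LAP, p_PVP,
#' p_DP)`. When the second step was not run (the phase was not identified as
#' AP) the AP mass is carried by the configured convention: `"eap_slot"`
#' (default) reports it unsplit in the EAP slot, i.e. split ratio (1, 0);
#' `"renormalize"` drops it and rescales the PVP/DP mass.
#'
#' @param step1 3-vector over (AP, PVP, DP), summing to 1 within 1e-6.
#' @param step2 2-vector over (EAP, LAP) or `NULL` when the second step was
#'   not activated.
#' @param ap_convention Convention for absent `step2` (see above).
#' @return 4-vector over (EAP, LAP, PVP, DP) summing to 1.
#' @export
compose_four_dim <- function(step1, step2 = NULL,
                             ap_convention = c("eap_slot", "renormalize")) {
  ap_convention <- match.arg(ap_convention)
  assert_that(length(step1) == 3 && abs(sum(step1) - 1) <= 1e-6,
              "step1 must be a 3-vector summing to 1")
  if (is.null(step2)) {
    out <- if (ap_convention == "eap_slot") {
      c(step1[1], 0, step1[2], step1[3])
    } else {
      c(0, 0, step1[2], step1[3]) / max(step1[2] + step1[3], 1e-12)
    }
  } else {
    assert_that(length(step2) == 2 && abs(sum(step2) - 1) <= 1e-6,
                "step2 must be a 2-vector summing to 1")
    out <- c(step1[1] * step2[1], step1[1] * step2[2], step1[2], step1[3])
  }
  setNames(as.numeric(out), PHASES4)
}

#' Two-step (cascaded) prediction
#'
#' Step 1 classifies every phase into AP/PVP/DP; the EAP-vs-LAP
#' sub-classifier is activated only if the first step identified at least one
#' AP, and runs only on those phases (a conditional check guards the second
#' step). Full 4-class vectors are assembled with [compose_four_dim()].
#'
#' @param exam An [examination()].
#' @param model3 3-class step-1 `phase_model` (or function).
#' @param model2 2-class EAP/LAP `phase_model` (or function); it receives a
#'   single-phase examination per argmax-AP phase.
#' @param calibrate Apply [calibrate_order()].
#' @param ap_convention Passed to [compose_four_dim()].
#' @return An `exam_prediction` tibble; the attribute `step2_invocations`
#'   records how many times the second-step model ran.
#' @export
predict_two_step <- function(exam, model3, model2, calibrate = TRUE,
                             ap_convention = "eap_slot") {
  assert_that(length(exam$phases) >= 1, "empty examination")
  p1 <- exam_probs(model3, exam)
  assert_that(ncol(p1) == 3, "two-step prediction needs a 3-class step-1 model")
  step1_labels <- PHASES_STEP1[apply(p1, 1, which.max)]
  n <- length(exam$phases)
  probs <- matrix(0, n, 4, dimnames = list(NULL, PHASES4))
  labels <- character(n)
  invocations <- 0L
  for (p in seq_len(n)) {
    if (step1_labels[p] == "AP") {
      sub <- examination(exam$phases[p], exam_id = exam$exam_id,
                         order_known = TRUE)
      p2 <- exam_probs(model2, sub)
      assert_that(ncol(p2) == 2, "second step needs a 2-class model")
      invocations <- invocations + 1L
      probs[p, ] <- compose_four_dim(p1[p, ], p2[1, ], ap_convention)
      labels[p] <- PHASES_AP[which.max(p2[1, ])]
    } else {
      probs[p, ] <- compose_four_dim(p1[p, ], NULL, ap_convention)
      labels[p] <- step1_labels[p]
    }
  }
  out <- assemble_prediction(exam, probs, labels, "two_step",
                             step2_invocations = invocations)
  if (calibrate) out <- calibrate_order(out, exam$order_known) else out
}

assemble_prediction <- function(exam, probs, labels, strategy,
                                step2_invocations = NA_integer_) {
  tbl <- tibble(
    exam_id = exam$exam_id,
    phase_index = seq_len(nrow(probs)),
    true_phase = true_phases(exam),
    acquisition_index = map_dbl(exam$phases,
                                function(p) p$acquisition_index %||% NA_real_),
    p_EAP = probs[, "EAP"], p_LAP = probs[, "LAP"],
    p_PVP = probs[, "PVP"], p_DP = probs[, "DP"],
    label_raw = labels,
    label_calibrated = labels,
    relative_order = rank_canonical(labels),
    strategy = strategy
  )
  new_exam_prediction(tbl, strategy, step2_invocations)
}

rank_canonical <- function(labels) {
  as.integer(rank(match(labels, PHASES4), ties.method = "first"))
}

# ordered arrangements of k distinct elements of x
arrangements <- function(x, k) {
  if (k == 1) return(map(x, function(e) e))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in arrangements(x[-i], k - 1)) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Calibrate exam labels with the phase-order prior
#'
#' One examination holds at most one acquisition per step-1 class (AP, PVP,
#' DP) in a canonical temporal order. Calibration brute-forces every
#' assignment of distinct step-1 classes to the exam's phases (at most
#' 3! = 6) and keeps the assignment maximizing the product of the predicted
#' class probabilities. When the acquisition order is known, assignments
#' violating it (AP before PVP before DP) are excluded. AP phases keep their
#' EAP/LAP refinement from the probability vector. If no feasible assignment
#' has positive probability, the raw argmax labels are kept with a warning.
#'
#' @param prediction An `exam_prediction` tibble (from [predict_one_step()]
#'   or [predict_two_step()]).
#' @param order_known Whether the row order is the acquisition order.
#' @return The prediction with `label_calibrated` and `relative_order`
#'   updated.
#' @export
calibrate_order <- function(prediction, order_known = FALSE) {
  n <- nrow(prediction)
  if (n < 2) return(prediction)
  p_step1 <- cbind(AP = prediction$p_EAP + prediction$p_LAP,
                   PVP = prediction$p_PVP, DP = prediction$p_DP)
  cand <- arrangements(PHASES_STEP1, n)
  if (order_known) {
    # acquisition order must respect canonical timing AP < PVP < DP
    ord <- if (!anyNA(prediction$acquisition_index)) {
      order(prediction$acquisition_index)
    } else seq_len(n)
    cand <- cand[map_lgl(cand, function(a) {
      !is.unsorted(match(a[ord], PHASES_STEP1))
    })]
  }
  joints <- map_dbl(cand, function(a) {
    prod(p_step1[cbind(seq_len(n), match(a, PHASES_STEP1))])
  })
  if (length(joints) == 0 || max(joints) <= 0) {
    warn("no feasible phase assignment with positive probability; keeping raw labels")
    best <- as_step1(prediction$label_raw)
  } else {
    best <- cand[[which.max(joints)]]
  }
  refined <- map_chr(seq_len(n), function(i) {
    if (best[i] == "AP") {
      PHASES_AP[which.max(c(prediction$p_EAP[i], prediction$p_LAP[i]))]
    } else best[i]
  })
  prediction$label_calibrated <- refined
  prediction$relative_order <- rank_canonical(refined)
  prediction
}

#' Bind exam predictions into one prediction table
#'
#' @param predictions List of `exam_prediction` tibbles.
#' @return A single tibble with all rows.
#' @export
bind_predictions <- function(predictions) {
  bind_rows(map(predictions, as_tibble))
}
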