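# On-disk formats: NIfTI-1 volumes, CSV manifests and prediction tables.

#' Write a cohort of examinations to disk
#'
#' Each phase volume goes to `<exam_id>_<phase|idx>.nii.gz` (spacing in the
#' NIfTI header) and a manifest CSV lists every phase.
#'
#' @param exams List of [examination()]s.
#' @param dir Output directory (created if needed).
#' @param manifest File name of the manifest CSV inside `dir`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(exams, dir, manifest = "manifest.csv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (ex in exams) {
    for (i in seq_along(ex$phases)) {
      ph <- ex$phases[[i]]
      tag <- ph$true_phase %||% sprintf("phase%d", i)
      file <- sprintf("%s_%s.nii.gz", ex$exam_id, tag)
      img <- RNifti::asNifti(ph$values)
      RNifti::pixdim(img) <- ph$spacing
      RNifti::writeNifti(img, file.path(dir, file))
      rows[[length(rows) + 1L]] <- tibble(
        exam_id = ex$exam_id, phase_file = file,
        true_phase = ph$true_phase %||% NA_character_,
        acquisition_index = ph$acquisition_index %||% NA_integer_)
    }
  }
  mpath <- file.path(dir, manifest)
  write.csv(bind_rows(rows), mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read and validate an examination manifest
#'
#' A manifest is a CSV (or JSON array of records) with columns `exam_id`,
#' `phase_file` and optionally `true_phase`, `acquisition_index`. Phases are
#' grouped by `exam_id` in listed order; `order_known` is true when the
#' `acquisition_index` column is present and complete for the exam. At most
#' 3 phases and at most one true label per step-1 class are allowed per
#' exam.
#'
#' @param path Manifest file path.
#' @return Tibble of validated manifest rows.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), paste0("manifest not found: ", path))
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    as_tibble(read.csv(path, stringsAsFactors = FALSE))
  }
  assert_that(all(c("exam_id", "phase_file") %in% names(m)),
              "manifest needs columns exam_id and phase_file")
  if (!"true_phase" %in% names(m)) m$true_phase <- NA_character_
  if (!"acquisition_index" %in% names(m)) m$acquisition_index <- NA_integer_
  m$true_phase[m$true_phase %in% c("", "NA")] <- NA_character_
  bad <- which(!is.na(m$true_phase) & !m$true_phase %in% PHASES4)
  assert_that(length(bad) == 0,
              paste0("unknown true_phase at manifest row(s) ",
                     paste(bad, collapse = ", ")))
  for (id in unique(m$exam_id)) {
    rows <- which(m$exam_id == id)
    assert_that(length(rows) <= 3,
                paste0("exam ", id, " has more than 3 phases (rows ",
                       paste(rows, collapse = ", "), ")"))
    labs <- m$true_phase[rows]
    s1 <- as_step1(labs[!is.na(labs)])
    assert_that(!anyDuplicated(s1),
                paste0("exam ", id, " duplicates a step-1 truth class (rows ",
                       paste(rows, collapse = ", "), ")"))
  }
  m
}

#' Load examinations listed in a manifest
#'
#' @param manifest Tibble from [read_manifest()] (or a manifest path).
#' @param dir Directory holding the phase files.
#' @return List of [examination()]s.
#' @export
load_exams <- function(manifest, dir = ".") {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  map(split(manifest, factor(manifest$exam_id, unique(manifest$exam_id))),
      function(rows) {
        phases <- map(seq_len(nrow(rows)), function(i) {
          path <- file.path(dir, rows$phase_file[i])
          assert_that(file.exists(path),
                      paste0("missing phase file (manifest row for exam ",
                             rows$exam_id[i], "): ", path))
          img <- RNifti::readNifti(path)
          tp <- rows$true_phase[i]
          phase_volume(array(as.numeric(img), dim = dim(img)),
                       spacing = RNifti::pixdim(img)[1:3],
                       exam_id = rows$exam_id[i],
                       true_phase = if (!is.na(tp)) tp,
                       acquisition_index = if (!is.na(rows$acquisition_index[i]))
                         rows$acquisition_index[i])
        })
        examination(phases, exam_id = rows$exam_id[1],
                    order_known = !anyNA(rows$acquisition_index))
      }) |> unname()
}

#' Write a prediction table to CSV
#'
#' @param predictions Tibble from [bind_predictions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.csv(as_tibble(predictions), path, row.names = FALSE)
  invisible(path)
}
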