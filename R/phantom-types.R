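#' Construct a CT phase volume
#'
#' A `phase_volume` is a 3D scalar grid of attenuation values in Hounsfield
#' units (HU) together with its voxel spacing and examination metadata. It is
#' the carrier object for one acquisition of one contrast phase.
#'
#' @param values 3D numeric array of HU values (finite, plausibly within
#'   \[-1024, 3071\]).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param exam_id Examination identifier (string).
#' @param true_phase Optional ground-truth phase, one of `"EAP"`, `"LAP"`,
#'   `"PVP"`, `"DP"` (or `"unenhanced"` for a baseline volume).
#' @param acquisition_index Optional integer acquisition order within the exam.
#'
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(values, spacing = c(1, 1, 1), exam_id = "exam",
                         true_phase = NULL, acquisition_index = NULL) {
  assert_that(is.array(values) && length(dim(values)) == 3,
              "`values` must be a 3D array")
  assert_that(all(is.finite(values)), "`values` must be finite")
  rng <- range(values)
  if (rng[1] < -1024 || rng[2] > 3071) {
    warn("HU values outside the plausible CT range [-1024, 3071]")
  }
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "`spacing` must be three positive numbers (mm)")
  if (!is.null(true_phase)) {
    assert_that(true_phase %in% c(PHASES4, "unenhanced"),
                "`true_phase` must be one of EAP, LAP, PVP, DP, unenhanced")
  }
  structure(
    list(values = values, spacing = as.numeric(spacing),
         exam_id = as.character(exam_id), true_phase = true_phase,
         acquisition_index = acquisition_index),
    class = "phase_volume"
  )
}

#' @export
print.phase_volume <- function(x, ...) {
  cat(sprintf("<phase_volume %s> %s  grid %s  spacing %s mm  HU [%.0f, %.0f]\n",
              x$exam_id, x$true_phase %||% "unlabelled",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a multi-phase examination
#'
#' One simulated (or real) patient examination: 1-3 co-registered phase
#' volumes, possibly in unknown acquisition order. At most one acquisition per
#' step-1 class (AP = EAP or LAP, PVP, DP) may carry a true label.
#'
#' @param phases List of [phase_volume()] objects (1 to 3).
#' @param exam_id Examination identifier; defaults to the first volume's.
#' @param order_known Logical; whether the listed order is the acquisition
#'   order.
#'
#' @return An object of class `examination`.
#' @export
examination <- function(phases, exam_id = NULL, order_known = TRUE) {
  assert_that(is.list(phases) && length(phases) >= 1 && length(phases) <= 3,
              "an examination holds 1 to 3 phase volumes")
  assert_that(all(map_lgl(phases, inherits, "phase_volume")),
              "`phases` must be a list of phase_volume objects")
  labels <- map_chr(phases, function(p) p$true_phase %||% NA_character_)
  step1 <- as_step1(labels[!is.na(labels)])
  assert_that(!anyDuplicated(step1),
              "at most one phase per step-1 class (AP, PVP, DP) per exam")
  exam_id <- exam_id %||% phases[[1]]$exam_id
  structure(
    list(exam_id = as.character(exam_id), phases = phases,
         order_known = isTRUE(order_known)),
    class = "examination"
  )
}

#' @export
print.examination <- function(x, ...) {
  labs <- map_chr(x$phases, function(p) p$true_phase %||% "?")
  cat(sprintf("<examination %s> %d phase(s): %s  (order %s)\n", x$exam_id,
              length(x$phases), paste(labs, collapse = ", "),
              if (x$order_known) "known" else "unknown"))
  invisible(x)
}

#' @export
length.examination <- function(x) length(x$phases)

# map a 4-class label to its step-1 class (EAP/LAP collapse to AP)
as_step1 <- function(label) {
  ifelse(label %in% PHASES_AP, "AP", label)
}

#' True phase labels of an examination
#'
#' @param exam An [examination()].
#' @return Character vector of per-phase true labels (NA where unlabelled).
#' @export
true_phases <- function(exam) {
  map_chr(exam$phases, function(p) p$true_phase %||% NA_character_)
}
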