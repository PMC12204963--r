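#' Window-normalize a CT volume
#'
#' Linearly maps the HU window `[WL - WW/2, WL + WW/2]` onto `[0, 1]`,
#' clamping values outside the window. The default window (WL 50 / WW 600) is
#' the uniform abdominal setting used for model input.
#'
#' @param volume A [phase_volume()] or a numeric array of HU values.
#' @param window_level Window level (centre) in HU.
#' @param window_width Window width in HU; must be positive.
#' @return Same shape as the input, values in `[0, 1]`. A `phase_volume`
#'   input keeps its metadata.
#' @export
window_normalize <- function(volume, window_level = 50, window_width = 600) {
  assert_that(window_width > 0, "window width must be positive")
  vals <- if (inherits(volume, "phase_volume")) volume$values else volume
  assert_that(all(is.finite(vals)), "HU values must be finite")
  out <- pmin(pmax((vals - (window_level - window_width / 2)) / window_width, 0), 1)
  if (inherits(volume, "phase_volume")) {
    volume$values <- out
    volume
  } else out
}

#' Trilinearly resample a volume onto a cubic target grid
#'
#' Cell-centred trilinear interpolation onto `target_shape`; when the target
#' equals the source shape the mapping is the identity. Output values stay
#' within the input range.
#'
#' @param volume A [phase_volume()] or 3D numeric array.
#' @param target_shape Integer length-3, every axis >= 8.
#' @return Resampled object of the same type, shape `target_shape`.
#' @export
resample_cubic <- function(volume, target_shape = c(192L, 192L, 192L)) {
  target_shape <- as.integer(target_shape)
  assert_that(length(target_shape) == 3 && all(target_shape >= 8),
              "target shape must have 3 axes, each >= 8")
  vals <- if (inherits(volume, "phase_volume")) volume$values else volume
  src <- dim(vals)
  assert_that(all(src >= 2),
              "cannot resample a degenerate (single-slice) axis; need >= 2 voxels per axis")
  coords <- map(1:3, function(a) {
    # cell-centred source coordinate of each target voxel centre
    x <- (seq_len(target_shape[a]) - 0.5) * src[a] / target_shape[a] + 0.5
    x <- pmin(pmax(x, 1), src[a])
    lo <- pmin(floor(x), src[a] - 1)
    list(lo = as.integer(lo), w = x - lo)
  })
  out <- array(0, dim = target_shape)
  # accumulate the 8 trilinear corners with outer-product weights
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 1) coords[[1]]$w else 1 - coords[[1]]$w
    wy <- if (dy == 1) coords[[2]]$w else 1 - coords[[2]]$w
    wz <- if (dz == 1) coords[[3]]$w else 1 - coords[[3]]$w
    block <- vals[coords[[1]]$lo + dx, coords[[2]]$lo + dy,
                  coords[[3]]$lo + dz, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + block * w
  }
  if (inherits(volume, "phase_volume")) {
    volume$spacing <- volume$spacing * src / target_shape
    volume$values <- out
    volume
  } else out
}

#' Randomly flip a volume along spatial axes
#'
#' Each spatial axis is flipped independently with probability `flip_prob`;
#' deterministic under the seed.
#'
#' @param volume A [phase_volume()] or 3D array.
#' @param rng_seed Integer seed.
#' @param flip_prob Per-axis flip probability.
#' @return Flipped object of the same type.
#' @export
augment_flip <- function(volume, rng_seed, flip_prob = 0.5) {
  axes <- with_seed(derive_seed(rng_seed, "flip"), runif(3) < flip_prob)
  apply_flip(volume, axes)
}

# flip selected axes of a volume/array (used so one exam's phases share flips)
apply_flip <- function(volume, axes) {
  vals <- if (inherits(volume, "phase_volume")) volume$values else volume
  d <- dim(vals)
  idx <- map(1:3, function(a) if (axes[a]) rev(seq_len(d[a])) else seq_len(d[a]))
  vals <- vals[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (inherits(volume, "phase_volume")) {
    volume$values <- vals
    volume
  } else vals
}

#' Flip all phases of an examination identically
#'
#' Applying the same flips to every phase preserves voxel-wise
#' co-registration, which the cross-phase attention relies on.
#'
#' @param exam An [examination()].
#' @inheritParams augment_flip
#' @return The flipped [examination()].
#' @export
augment_flip_exam <- function(exam, rng_seed, flip_prob = 0.5) {
  axes <- with_seed(derive_seed(rng_seed, "flip"), runif(3) < flip_prob)
  exam$phases <- map(exam$phases, apply_flip, axes = axes)
  exam
}

#' Randomly drop phases from an examination
#'
#' Simulates exams with fewer than three acquired phases: keeps a uniformly
#' chosen non-empty subset of at least `keep_min` phases; true labels travel
#' with the retained volumes.
#'
#' @param exam An [examination()].
#' @param rng_seed Integer seed.
#' @param keep_min Minimum number of phases to keep.
#' @return An [examination()] with a subset of the phases.
#' @export
drop_phases <- function(exam, rng_seed, keep_min = 1L) {
  n <- length(exam$phases)
  assert_that(keep_min >= 1 && keep_min <= n,
              "keep_min must be between 1 and the number of phases")
  keep <- with_seed(derive_seed(rng_seed, "drop"), {
    sizes <- seq.int(keep_min, n)
    k <- sizes[sample.int(length(sizes), 1)]
    sort(sample(n, k))
  })
  exam$phases <- exam$phases[keep]
  exam
}

#' Shuffle the phase order of an examination
#'
#' Permutes the phases uniformly at random and marks the order unknown;
#' labels travel with their volumes. Classification is order-free, so this is
#' a training-time robustness perturbation.
#'
#' @param exam An [examination()].
#' @param rng_seed Integer seed.
#' @return The permuted [examination()] with `order_known = FALSE`.
#' @export
shuffle_phase_order <- function(exam, rng_seed) {
  n <- length(exam$phases)
  perm <- with_seed(derive_seed(rng_seed, "shuffle"), sample(n))
  exam$phases <- exam$phases[perm]
  exam$order_known <- FALSE
  exam
}

#' Preprocess an examination for the network
#'
#' Window-normalizes and resamples every phase to the model's cubic input
#' grid.
#'
#' @param exam An [examination()].
#' @param target_shape Cubic model input shape.
#' @param window_level,window_width HU window.
#' @return The preprocessed [examination()] (values in `[0,1]`).
#' @export
preprocess_exam <- function(exam, target_shape = c(192L, 192L, 192L),
                            window_level = 50, window_width = 600) {
  exam$phases <- map(exam$phases, function(p) {
    resample_cubic(window_normalize(p, window_level, window_width),
                   target_shape)
  })
  exam
}
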