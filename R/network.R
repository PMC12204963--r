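# Cross-phase attention fusion and the exam-level forward/backward pass.

#' Cross-phase attention term
#'
#' Computes `f(A, B) = A %*% softmax(-t(A) %*% B)`: the channel affinity
#' `G = t(A) %*% B` (C x C, over flattened spatial positions) is negated,
#' softmaxed row-wise, and used to re-mix the channels of `A`. Negating the
#' affinity down-weights channels that agree across phases, accentuating
#' inter-phase differences. The output has the shape of `A`.
#'
#' @param A,B Feature-map matrices (N spatial positions x C channels) of
#'   identical shape, finite entries.
#' @param scale If `TRUE`, divide the affinity by `sqrt(N)` before the
#'   softmax.
#' @return N x C matrix.
#' @export
attention_term <- function(A, B, scale = FALSE) {
  fw <- attention_forward(A, B, scale)
  fw$out
}

attention_forward <- function(A, B, scale = FALSE) {
  assert_that(is.matrix(A) && is.matrix(B) && identical(dim(A), dim(B)),
              "A and B must be matrices of identical shape")
  assert_that(all(is.finite(A)) && all(is.finite(B)),
              "attention operands must be finite")
  G <- crossprod(A, B)
  if (scale) G <- G / sqrt(nrow(A))
  S <- softmax_rows(-G)
  list(out = A %*% S, S = S)
}

attention_backward <- function(dout, A, B, S, scale = FALSE) {
  dA <- tcrossprod(dout, S)
  dS <- crossprod(A, dout)
  dG <- -S * (dS - rowSums(dS * S))
  if (scale) dG <- dG / sqrt(nrow(A))
  list(dA = dA + B %*% t(dG), dB = A %*% dG)
}

#' Fuse per-phase feature maps by cross-phase attention
#'
#' For each phase `p`, `F'_p = F_p + sum over other phases q of
#' attention_term(F_p, F_q)`. With a single phase the sum is empty and the
#' features pass through unchanged; with missing phases the sum runs over the
#' phases present.
#'
#' @param features Named or unnamed list of 1-3 feature-map matrices of
#'   identical shape.
#' @param scale Passed to [attention_term()].
#' @return List of fused feature maps, same names/shapes as the input.
#' @export
fuse_features <- function(features, scale = FALSE) {
  fw <- fuse_forward(features, scale)
  fw$fused
}

fuse_forward <- function(features, scale = FALSE) {
  n <- length(features)
  assert_that(n >= 1 && n <= 3, "fusion takes 1 to 3 feature maps")
  dims <- map(features, dim)
  assert_that(all(map_lgl(dims, identical, dims[[1]])),
              "all feature maps must share the same shape")
  terms <- vector("list", n)
  fused <- features
  for (p in seq_len(n)) {
    terms[[p]] <- list()
    for (q in seq_len(n)) {
      if (q == p) next
      at <- attention_forward(features[[p]], features[[q]], scale)
      fused[[p]] <- fused[[p]] + at$out
      terms[[p]][[as.character(q)]] <- at$S
    }
  }
  list(fused = fused, S = terms)
}

fuse_backward <- function(dfused, features, S, scale = FALSE) {
  n <- length(features)
  dF <- map(features, function(f) f * 0)
  for (p in seq_len(n)) {
    dF[[p]] <- dF[[p]] + dfused[[p]]
    for (q in seq_len(n)) {
      if (q == p) next
      ab <- attention_backward(dfused[[p]], features[[p]], features[[q]],
                               S[[p]][[as.character(q)]], scale)
      dF[[p]] <- dF[[p]] + ab$dA
      dF[[q]] <- dF[[q]] + ab$dB
    }
  }
  dF
}

#' Extract mid-level features for one volume
#'
#' Runs the shared extractor up to (and including) the attention stage and
#' returns the flattened feature map. Because every phase branch uses the
#' same parameter set, identical volumes always yield identical feature maps.
#'
#' @param volume A preprocessed [phase_volume()] (values in `[0,1]`) or a 3D
#'   array matching the network input shape.
#' @param net A [phase_net()].
#' @return N x C feature-map matrix with attribute `phase` (the volume's
#'   label, if any).
#' @export
extract_features <- function(volume, net) {
  vals <- if (inherits(volume, "phase_volume")) volume$values else volume
  fr <- front_forward(net, vals)
  out <- fr$F
  attr(out, "phase") <- if (inherits(volume, "phase_volume")) volume$true_phase
  out
}

#' Softmax classification head
#'
#' Global-average-pooled features through a fully connected layer and
#' softmax. The output is a probability vector: non-negative, summing to 1.
#'
#' @param features Feature vector (length C), or an N x C matrix that is
#'   average-pooled over rows first.
#' @param W C x n_classes weight matrix.
#' @param b Length-n_classes bias.
#' @return Probability vector of length `n_classes`.
#' @export
classify_head <- function(features, W, b = numeric(ncol(W))) {
  feat <- if (is.matrix(features)) colMeans(features) else features
  assert_that(length(feat) == nrow(W), "feature length must match nrow(W)")
  softmax_vec(as.numeric(matrix(feat, 1) %*% W) + b)
}

#' Forward pass of a full examination
#'
#' Runs every phase through the shared-parameter extractor to the attention
#' stage, fuses the per-phase feature maps by cross-phase attention, then
#' continues through the remaining stages and the softmax head, again with
#' shared parameters. The computation is symmetric in the phases, so
#' permuting the input order permutes the output rows identically.
#'
#' @param exam An [examination()] with preprocessed phases, or a list of 3D
#'   arrays / [phase_volume()]s matching the network input shape.
#' @param net A [phase_net()].
#' @param keep_tape Keep intermediate activations for a backward pass
#'   (training use).
#' @return Matrix of per-phase probability rows (columns named by the
#'   network's classes). With `keep_tape = TRUE`, a list `(probs, tape)`.
#' @export
forward_exam <- function(exam, net, keep_tape = FALSE) {
  vols <- exam_values(exam)
  n <- length(vols)
  assert_that(n >= 1, "examination has no phases")
  fronts <- map(vols, function(v) front_forward(net, v))
  feats <- map(fronts, "F")
  fw <- fuse_forward(feats, net$config$attention_scale)
  tails <- map(seq_len(n), function(p) {
    tail_forward(net, fw$fused[[p]], fronts[[p]]$spatial)
  })
  probs <- do.call(rbind, map(tails, "probs"))
  colnames(probs) <- net$config$classes
  if (!keep_tape) return(probs)
  list(probs = probs,
       tape = list(fronts = fronts, feats = feats, fuse = fw, tails = tails))
}

exam_values <- function(exam) {
  vols <- if (inherits(exam, "examination")) exam$phases else exam
  if (!is.list(vols)) vols <- list(vols)
  map(vols, function(v) if (inherits(v, "phase_volume")) v$values else v)
}

# Backward pass of one exam given per-phase dlogits rows; returns the flat
# gradient list (summed over phases; shared parameters accumulate).
backward_exam <- function(net, tape, dlogits_rows) {
  n <- length(tape$tails)
  grads <- list()
  dfused <- vector("list", n)
  for (p in seq_len(n)) {
    tb <- tail_backward(net, dlogits_rows[p, ], tape$tails[[p]], grads)
    grads <- tb$grads
    dfused[[p]] <- tb$dF
  }
  dF <- fuse_backward(dfused, tape$feats, tape$fuse$S,
                      net$config$attention_scale)
  for (p in seq_len(n)) {
    grads <- front_backward(net, dF[[p]], tape$fronts[[p]], grads)
  }
  grads
}
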