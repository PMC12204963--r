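# Shared fixtures: tiny network configurations, naive reference
# implementations of the attention fusion, and small phantom builders.

tiny_net_config <- function(n_classes = 3L, input = 8L) {
  net_config(NULL, input_shape = rep(input, 3), stem_channels = 2L,
             stage_channels = c(2L, 3L), blocks_per_stage = c(1L, 1L),
             stage_strides = c(1L, 2L), attention_stage = 1L,
             n_classes = n_classes)
}

tiny_volume <- function(seed, input = 8L) {
  set.seed(seed)
  array(runif(input^3), rep(input, 3))
}

# Naive double-loop reference for the attention term and fusion: computes
# G = t(A) B, row softmax of -G and A %*% S with explicit loops.
naive_attention <- function(A, B) {
  C <- ncol(A)
  G <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    G[i, j] <- sum(A[, i] * B[, j])
  }
  S <- matrix(0, C, C)
  for (i in seq_len(C)) {
    e <- exp(-G[i, ] - max(-G[i, ]))
    S[i, ] <- e / sum(e)
  }
  out <- matrix(0, nrow(A), C)
  for (r in seq_len(nrow(A))) for (j in seq_len(C)) {
    out[r, j] <- sum(A[r, ] * S[, j])
  }
  out
}

naive_fusion <- function(feats) {
  n <- length(feats)
  out <- feats
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (q != p) out[[p]] <- out[[p]] + naive_attention(feats[[p]], feats[[q]])
    }
  }
  out
}

# small labelled phantom exam on the default 32^3 grid
small_exam <- function(labels = c("LAP", "PVP", "DP"), seed = 1) {
  make_phantom_exam(phantom_spec(), enhancement_profile(), labels, seed)
}

# step-1 truth of an exam
step1_truth <- function(exam) {
  ifelse(true_phases(exam) %in% c("EAP", "LAP"), "AP", true_phases(exam))
}
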