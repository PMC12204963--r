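test_that("attention term matches hand-derived values", {
  # singleton: softmax over one channel is 1, so the output is A itself
  expect_equal(attention_term(matrix(3.2), matrix(-1)), matrix(3.2))
  # 2x2 identity operands: G = I, rows of S = softmax(-row of G)
  A <- diag(2)
  out <- attention_term(A, A)
  s <- exp(c(-1, 0)) / sum(exp(c(-1, 0)))
  expect_equal(out, rbind(s, rev(s)), ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(out[1, ], c(0.2689, 0.7311), tolerance = 1e-3)
  expect_error(attention_term(matrix(1), matrix(1:2)), "identical shape")
  expect_error(attention_term(matrix(NaN), matrix(1)), "finite")
})

test_that("attention and fusion match the naive loop reference on random tensors", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    C <- sample(2:8, 1)
    A <- matrix(rnorm(n * C), n, C)
    B <- matrix(rnorm(n * C), n, C)
    expect_equal(attention_term(A, B), naive_attention(A, B), tolerance = 1e-6)
    # softmax rows of the attention matrix sum to 1
    S <- attention_forward(A, B)$S
    expect_equal(rowSums(S), rep(1, C), tolerance = 1e-6)
    k <- sample(1:3, 1)
    feats <- lapply(seq_len(k), function(i) matrix(rnorm(n * C), n, C))
    expect_equal(fuse_features(feats), naive_fusion(feats), tolerance = 1e-6)
  }
})

test_that("fusion is the identity for a single phase and adds one term per other phase", {
  F1 <- matrix(rnorm(12), 4, 3)
  expect_identical(fuse_features(list(F1))[[1]], F1)
  F2 <- matrix(rnorm(12), 4, 3)
  two <- fuse_features(list(F1, F2))
  expect_equal(two[[1]], F1 + attention_term(F1, F2), tolerance = 1e-12)
  expect_equal(two[[2]], F2 + attention_term(F2, F1), tolerance = 1e-12)
  expect_error(fuse_features(list(F1, matrix(0, 2, 2))), "same shape")
})

test_that("shared parameters make identical volumes yield identical features", {
  net <- phase_net(tiny_net_config(), seed = 3)
  v <- tiny_volume(7)
  f1 <- extract_features(v, net)
  f2 <- extract_features(v, net)
  expect_identical(unclass(f1), unclass(f2))
  # shape contract: N spatial positions x C channels of the attention stage
  expect_equal(dim(f1), c(4^3, 2))
  # zero input with zero biases gives zero features
  zn <- net
  zn$params <- lapply(zn$params, function(p) p * 0)
  fz <- extract_features(array(0, c(8, 8, 8)), zn)
  expect_true(all(fz == 0))
})

test_that("classification heads emit shift-invariant probability vectors", {
  W <- matrix(rnorm(12), 3, 4)
  feat <- rnorm(3)
  p <- classify_head(feat, W)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  # zero weights -> zero logits -> uniform
  expect_equal(classify_head(feat, W * 0), rep(0.25, 4))
  # adding a constant to all logits leaves the softmax unchanged
  expect_equal(classify_head(feat, W, b = rep(5, 4)), p, tolerance = 1e-12)
  # matrix features are average-pooled over positions first
  fm <- matrix(rep(feat, each = 10), 10, 3)
  expect_equal(classify_head(fm, W), p)
})

test_that("forward_exam is permutation-equivariant and duplicate-symmetric", {
  net <- phase_net(tiny_net_config(), seed = 9)
  vols <- list(tiny_volume(1), tiny_volume(2), tiny_volume(3))
  base <- forward_exam(vols, net)
  expect_equal(rowSums(base), rep(1, 3), tolerance = 1e-6)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (pm in perms) {
    out <- forward_exam(vols[pm], net)
    expect_equal(out, base[pm, ], tolerance = 1e-10)
  }
  # duplicated volumes produce identical probability rows
  dup <- forward_exam(list(vols[[1]], vols[[1]]), net)
  expect_equal(dup[1, ], dup[2, ], tolerance = 1e-12)
  # a single-phase exam equals a plain no-attention forward pass
  single <- forward_exam(vols[1], net)
  fr <- front_forward(net, vols[[1]])
  plain <- tail_forward(net, fr$F, fr$spatial)$probs
  expect_equal(as.numeric(single), plain, tolerance = 1e-12)
  expect_error(forward_exam(list(), net), "no phases")
})

test_that("exam backward pass matches numerical gradients", {
  net <- phase_net(tiny_net_config(), seed = 5)
  vols <- list(tiny_volume(4), tiny_volume(5))
  targets <- c(1, 3)
  loss_of <- function(nt) {
    p <- forward_exam(vols, nt)
    sum(vapply(1:2, function(i) focal_loss(p[i, ], targets[i], 2), 0))
  }
  fw <- forward_exam(vols, net, keep_tape = TRUE)
  dl <- t(vapply(1:2, function(i) focal_dlogits(fw$probs[i, ], targets[i], 2),
                 numeric(3)))
  g <- backward_exam(net, fw$tape, dl)
  set.seed(8)
  for (nm in c("stem.W", "s1b1.conv1.W", "s2b1.proj.W", "fc.W", "fc.b")) {
    i <- sample(length(net$params[[nm]]), 1)
    eps <- 1e-5
    up <- net
    up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- net
    dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
    expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-5)
  }
})

test_that("network configuration is validated", {
  expect_error(net_config(NULL, input_shape = c(8, 8, 8), stem_channels = 2,
                          stage_channels = c(2, 3), blocks_per_stage = c(1, 1),
                          stage_strides = c(1, 2), attention_stage = 2,
                          n_classes = 3),
               "interior")
  expect_error(net_config("desk", n_classes = 5), "n_classes")
  cfg <- net_config("full")
  expect_equal(cfg$input_shape, c(192L, 192L, 192L))
  expect_equal(cfg$stage_channels, c(64L, 128L, 256L, 512L))
  expect_equal(sum(cfg$blocks_per_stage), 8L)
  net <- phase_net(tiny_net_config(), seed = 1)
  expect_error(forward_exam(list(array(0, c(4, 4, 4))), net), "input shape")
})
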