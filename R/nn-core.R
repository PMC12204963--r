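# Minimal 3D convolutional network engine (forward + reverse-mode gradients).
# Feature tensors are 4D arrays (D, H, W, C); convolutions run as im2col
# gathers followed by BLAS matrix multiplies. Parameters live in a flat named
# list so the optimiser can walk them generically.

# --- im2col / col2im -------------------------------------------------------

conv_out_shape <- function(in_sp, k, stride, pad) {
  (in_sp + 2L * pad - k) %/% stride + 1L
}

# Gather indices of the padded input for every (kernel offset, channel)
# column of the im2col matrix, cached per (shape, kernel, stride, pad) so a
# training run pays the construction cost once per layer geometry.
.conv_cache <- new.env(parent = emptyenv())

conv_index <- function(in_dim, k, stride, pad) {
  key <- paste(c(in_dim, k, stride, pad), collapse = "x")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  pd <- c(in_dim[1:3] + 2L * pad, in_dim[4])
  osp <- conv_out_shape(in_dim[1:3], k, stride, pad)
  n <- prod(osp)
  C <- in_dim[4]
  plane <- prod(pd[1:3])
  idx <- matrix(0L, n, k^3 * C)
  kk <- 0L
  for (dz in 0:(k - 1)) for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    i1 <- seq.int(1L + dx, by = stride, length.out = osp[1])
    i2 <- seq.int(1L + dy, by = stride, length.out = osp[2])
    i3 <- seq.int(1L + dz, by = stride, length.out = osp[3])
    base <- as.integer(outer(outer(i1, (i2 - 1L) * pd[1], `+`),
                             (i3 - 1L) * pd[1] * pd[2], `+`))
    for (ch in seq_len(C)) {
      idx[, kk * C + ch] <- base + (ch - 1L) * plane
    }
    kk <- kk + 1L
  }
  out <- list(idx = as.integer(idx), pd = pd, osp = osp, n = n,
              blocks = map(seq_len(k^3), function(kk) {
                as.integer(idx[, (kk - 1L) * C + seq_len(C)])
              }))
  .conv_cache[[key]] <- out
  out
}

im2col <- function(x, k, stride, pad) {
  d <- dim(x)
  ci <- conv_index(d, k, stride, pad)
  if (pad > 0) {
    xp <- array(0, dim = ci$pd)
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  } else {
    xp <- x
  }
  mat <- xp[ci$idx]
  dim(mat) <- c(ci$n, k^3 * d[4])
  list(mat = mat, out_sp = ci$osp)
}

col2im <- function(dmat, in_dim, k, stride, pad, osp) {
  ci <- conv_index(in_dim, k, stride, pad)
  C <- in_dim[4]
  dxp <- numeric(prod(ci$pd))
  for (kk in seq_len(k^3)) {
    iv <- ci$blocks[[kk]]
    dxp[iv] <- dxp[iv] + dmat[, (kk - 1L) * C + seq_len(C)]
  }
  dim(dxp) <- ci$pd
  if (pad > 0) {
    dxp[pad + seq_len(in_dim[1]), pad + seq_len(in_dim[2]),
        pad + seq_len(in_dim[3]), , drop = FALSE]
  } else {
    dxp
  }
}

# --- layer primitives ------------------------------------------------------

conv3d_forward <- function(x, W, b, k, stride, pad) {
  ic <- im2col(x, k, stride, pad)
  y <- ic$mat %*% W
  y <- sweep(y, 2, b, `+`)
  list(out = array(y, dim = c(ic$out_sp, ncol(W))),
       cache = list(mat = ic$mat, in_dim = dim(x), out_sp = ic$out_sp))
}

conv3d_backward <- function(dout, W, k, stride, pad, cache) {
  n <- nrow(cache$mat)
  dmat_out <- matrix(dout, n, ncol(W))
  dW <- crossprod(cache$mat, dmat_out)
  db <- colSums(dmat_out)
  dx <- col2im(dmat_out %*% t(W), cache$in_dim, k, stride, pad, cache$out_sp)
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

# Per-channel spatial normalization with learned scale/shift (the batch-1
# form of the batch normalization used in residual networks): each channel's
# spatial map is standardized over its positions.
norm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  n <- prod(d[1:3])
  m <- matrix(x, n, d[4])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  sigma <- sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2, sigma, `/`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = array(y, dim = d), cache = list(xhat = xhat, sigma = sigma,
                                             dim = d))
}

norm_backward <- function(dout, gamma, cache) {
  d <- cache$dim
  n <- prod(d[1:3])
  dy <- matrix(dout, n, d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  coef <- sweep(dy, 2, dbeta / n) - sweep(xhat, 2, dgamma / n, `*`)
  dx <- sweep(coef, 2, gamma / cache$sigma, `*`)
  list(dx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# dz from upstream dp through p = softmax(z)
softmax_vec_backward <- function(dp, p) {
  p * (dp - sum(dp * p))
}

# --- architecture ----------------------------------------------------------

#' Feature-extractor / classifier configuration
#'
#' Describes an 18-layer-style residual 3D convolutional network: a strided
#' stem convolution, residual stages (basic blocks of two 3x3x3 convolutions
#' with identity or projected shortcuts), cross-phase attention fusion after
#' an interior stage, global average pooling and a softmax head. Presets:
#' `"full"` is the full-size configuration (192^3 input, stages
#' 64/128/256/512 with two blocks each, fusion after stage 2); `"desk"` is a
#' CPU-scale miniature (32^3 input); `"micro"` is smaller still (16^3 input)
#' for fast multi-seed experiments.
#'
#' @param preset One of `"desk"`, `"micro"`, `"full"`, or `NULL` to use the
#'   explicit arguments.
#' @param input_shape Cubic input grid.
#' @param stem_channels Channels of the stem convolution (stride 2).
#' @param stage_channels Integer vector of channels per residual stage.
#' @param blocks_per_stage Residual blocks per stage.
#' @param stage_strides Stride of each stage's first block.
#' @param attention_stage Interior stage index after which cross-phase
#'   attention fusion is applied.
#' @param n_classes Head size (2, 3 or 4).
#' @param classes Class labels; defaults follow `n_classes`.
#' @param attention_scale If `TRUE`, scale the channel affinity by
#'   `1/sqrt(N)` before the softmax (off by default).
#' @return A list of class `net_config`.
#' @export
net_config <- function(preset = "desk", input_shape = NULL,
                       stem_channels = NULL, stage_channels = NULL,
                       blocks_per_stage = NULL, stage_strides = NULL,
                       attention_stage = NULL, n_classes = 3L,
                       classes = NULL, attention_scale = FALSE) {
  defaults <- switch(
    preset %||% "custom",
    desk = list(input_shape = c(32L, 32L, 32L), stem_channels = 8L,
                stage_channels = c(8L, 16L, 32L), blocks_per_stage = c(1L, 1L, 1L),
                stage_strides = c(1L, 2L, 2L), attention_stage = 2L),
    micro = list(input_shape = c(16L, 16L, 16L), stem_channels = 6L,
                 stage_channels = c(6L, 12L), blocks_per_stage = c(1L, 1L),
                 stage_strides = c(1L, 2L), attention_stage = 1L),
    full = list(input_shape = c(192L, 192L, 192L), stem_channels = 64L,
                 stage_channels = c(64L, 128L, 256L, 512L),
                 blocks_per_stage = c(2L, 2L, 2L, 2L),
                 stage_strides = c(1L, 2L, 2L, 2L), attention_stage = 2L),
    custom = list()
  )
  cfg <- list(
    input_shape = as.integer(input_shape %||% defaults$input_shape),
    stem_channels = as.integer(stem_channels %||% defaults$stem_channels),
    stage_channels = as.integer(stage_channels %||% defaults$stage_channels),
    blocks_per_stage = as.integer(blocks_per_stage %||% defaults$blocks_per_stage),
    stage_strides = as.integer(stage_strides %||% defaults$stage_strides),
    attention_stage = as.integer(attention_stage %||% defaults$attention_stage),
    n_classes = as.integer(n_classes),
    attention_scale = isTRUE(attention_scale)
  )
  cfg$classes <- classes %||% switch(as.character(cfg$n_classes),
                                     "2" = PHASES_AP,
                                     "3" = PHASES_STEP1,
                                     "4" = PHASES4)
  ns <- length(cfg$stage_channels)
  assert_that(ns >= 2 && length(cfg$blocks_per_stage) == ns &&
                length(cfg$stage_strides) == ns,
              "stage_channels, blocks_per_stage and stage_strides must agree and define >= 2 stages")
  assert_that(cfg$attention_stage >= 1 && cfg$attention_stage < ns,
              "attention_stage must be an interior stage")
  assert_that(all(cfg$stage_channels > 0), "channel counts must be positive")
  assert_that(cfg$n_classes %in% 2:4, "n_classes must be 2, 3 or 4")
  assert_that(length(cfg$classes) == cfg$n_classes, "classes must match n_classes")
  structure(cfg, class = "net_config")
}

he_init <- function(fan_in, n) rnorm(n, 0, sqrt(2 / fan_in))

conv_desc <- function(name, c_in, c_out, k, stride) {
  list(name = name, c_in = c_in, c_out = c_out, k = k, stride = stride,
       pad = if (k > 1) (k - 1L) %/% 2L else 0L)
}

init_conv_params <- function(params, d) {
  fan <- d$k^3 * d$c_in
  params[[paste0(d$name, ".W")]] <- matrix(he_init(fan, fan * d$c_out),
                                           fan, d$c_out)
  params[[paste0(d$name, ".b")]] <- numeric(d$c_out)
  # per-channel normalization scale/shift following every convolution
  params[[paste0(d$name, ".g")]] <- rep(1, d$c_out)
  params[[paste0(d$name, ".s")]] <- numeric(d$c_out)
  params
}

#' Initialise a phase-classification network
#'
#' @param config A [net_config()].
#' @param seed Integer seed for He-style weight initialisation.
#' @return An object of class `phase_net` holding the architecture
#'   description and a flat parameter list.
#' @export
phase_net <- function(config = net_config(), seed = 1L) {
  cfg <- config
  arch <- list()
  arch$stem <- conv_desc("stem", 1L, cfg$stem_channels, 3L, 2L)
  c_in <- cfg$stem_channels
  arch$stages <- list()
  for (s in seq_along(cfg$stage_channels)) {
    c_out <- cfg$stage_channels[s]
    blocks <- list()
    for (b in seq_len(cfg$blocks_per_stage[s])) {
      stride <- if (b == 1L) cfg$stage_strides[s] else 1L
      nm <- sprintf("s%db%d", s, b)
      blk <- list(
        conv1 = conv_desc(paste0(nm, ".conv1"), c_in, c_out, 3L, stride),
        conv2 = conv_desc(paste0(nm, ".conv2"), c_out, c_out, 3L, 1L),
        proj = if (stride != 1L || c_in != c_out) {
          conv_desc(paste0(nm, ".proj"), c_in, c_out, 1L, stride)
        }
      )
      blocks[[b]] <- blk
      c_in <- c_out
    }
    arch$stages[[s]] <- blocks
  }
  params <- with_seed(derive_seed(seed, "init"), {
    p <- list()
    p <- init_conv_params(p, arch$stem)
    for (st in arch$stages) for (blk in st) {
      p <- init_conv_params(p, blk$conv1)
      p <- init_conv_params(p, blk$conv2)
      if (!is.null(blk$proj)) p <- init_conv_params(p, blk$proj)
    }
    c_last <- utils::tail(cfg$stage_channels, 1)
    p[["fc.W"]] <- matrix(he_init(c_last, c_last * cfg$n_classes),
                          c_last, cfg$n_classes)
    p[["fc.b"]] <- numeric(cfg$n_classes)
    p
  })
  structure(list(config = cfg, arch = arch, params = params),
            class = "phase_net")
}

#' @export
print.phase_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<phase_net> input %s, stem %d, stages %s (blocks %s), attention after stage %d, %d-class head (%s)\n",
    paste(cfg$input_shape, collapse = "x"), cfg$stem_channels,
    paste(cfg$stage_channels, collapse = "/"),
    paste(cfg$blocks_per_stage, collapse = "/"),
    cfg$attention_stage, cfg$n_classes, paste(cfg$classes, collapse = ", ")))
  cat(sprintf("  %d parameters\n", sum(map_dbl(x$params, length))))
  invisible(x)
}

n_params <- function(net) sum(map_dbl(net$params, length))

# --- forward/backward through arch pieces ----------------------------------

# convolution followed by its per-channel normalization
run_conv <- function(x, d, params) {
  cv <- conv3d_forward(x, params[[paste0(d$name, ".W")]],
                       params[[paste0(d$name, ".b")]], d$k, d$stride, d$pad)
  nm <- norm_forward(cv$out, params[[paste0(d$name, ".g")]],
                     params[[paste0(d$name, ".s")]])
  list(out = nm$out, cache = list(conv = cv$cache, norm = nm$cache))
}

back_conv <- function(dout, d, params, cache, grads) {
  nb <- norm_backward(dout, params[[paste0(d$name, ".g")]], cache$norm)
  g <- conv3d_backward(nb$dx, params[[paste0(d$name, ".W")]], d$k, d$stride,
                       d$pad, cache$conv)
  for (pair in list(c("W", "dW"), c("b", "db"))) {
    nm <- paste0(d$name, ".", pair[1])
    grads[[nm]] <- (grads[[nm]] %||% 0) + g[[pair[2]]]
  }
  gn <- paste0(d$name, ".g"); sn <- paste0(d$name, ".s")
  grads[[gn]] <- (grads[[gn]] %||% 0) + nb$dgamma
  grads[[sn]] <- (grads[[sn]] %||% 0) + nb$dbeta
  list(dx = g$dx, grads = grads)
}

block_forward <- function(x, blk, params) {
  c1 <- run_conv(x, blk$conv1, params)
  r1 <- relu_forward(c1$out)
  c2 <- run_conv(r1$out, blk$conv2, params)
  if (is.null(blk$proj)) {
    sc <- list(out = x, cache = NULL)
  } else {
    sc <- run_conv(x, blk$proj, params)
  }
  r2 <- relu_forward(c2$out + sc$out)
  list(out = r2$out,
       cache = list(c1 = c1$cache, m1 = r1$mask, c2 = c2$cache,
                    sc = sc$cache, m2 = r2$mask))
}

block_backward <- function(dout, blk, params, cache, grads) {
  d <- dout * cache$m2
  b2 <- back_conv(d, blk$conv2, params, cache$c2, grads)
  grads <- b2$grads
  d1 <- b2$dx * cache$m1
  b1 <- back_conv(d1, blk$conv1, params, cache$c1, grads)
  grads <- b1$grads
  if (is.null(blk$proj)) {
    dx <- b1$dx + d
  } else {
    bp <- back_conv(d, blk$proj, params, cache$sc, grads)
    grads <- bp$grads
    dx <- b1$dx + bp$dx
  }
  list(dx = dx, grads = grads)
}

# stem + stages 1..attention_stage; returns the flattened feature map (N x C)
front_forward <- function(net, vol3d) {
  assert_that(identical(dim(vol3d), net$config$input_shape),
              "volume shape does not match the network input shape")
  x <- array(vol3d, dim = c(dim(vol3d), 1L))
  st <- run_conv(x, net$arch$stem, net$params)
  r <- relu_forward(st$out)
  caches <- list(stem = st$cache, stem_mask = r$mask, blocks = list())
  x <- r$out
  for (s in seq_len(net$config$attention_stage)) {
    for (b in seq_along(net$arch$stages[[s]])) {
      bf <- block_forward(x, net$arch$stages[[s]][[b]], net$params)
      caches$blocks[[length(caches$blocks) + 1L]] <- bf$cache
      x <- bf$out
    }
  }
  sp <- dim(x)
  list(F = matrix(x, prod(sp[1:3]), sp[4]), spatial = sp, caches = caches)
}

front_backward <- function(net, dF, front, grads) {
  dx <- array(dF, dim = front$spatial)
  ci <- length(front$caches$blocks)
  for (s in rev(seq_len(net$config$attention_stage))) {
    for (b in rev(seq_along(net$arch$stages[[s]]))) {
      bb <- block_backward(dx, net$arch$stages[[s]][[b]], net$params,
                           front$caches$blocks[[ci]], grads)
      dx <- bb$dx
      grads <- bb$grads
      ci <- ci - 1L
    }
  }
  dx <- dx * front$caches$stem_mask
  bs <- back_conv(dx, net$arch$stem, net$params, front$caches$stem, grads)
  bs$grads
}

# stages attention_stage+1..end + GAP + fc + softmax, from a fused map
tail_forward <- function(net, Fmat, spatial) {
  x <- array(Fmat, dim = spatial)
  caches <- list(blocks = list())
  ns <- length(net$arch$stages)
  for (s in seq.int(net$config$attention_stage + 1L, ns)) {
    for (b in seq_along(net$arch$stages[[s]])) {
      bf <- block_forward(x, net$arch$stages[[s]][[b]], net$params)
      caches$blocks[[length(caches$blocks) + 1L]] <- bf$cache
      x <- bf$out
    }
  }
  sp <- dim(x)
  n_sp <- prod(sp[1:3])
  feat <- colMeans(matrix(x, n_sp, sp[4]))
  logits <- as.numeric(matrix(feat, 1) %*% net$params[["fc.W"]]) +
    net$params[["fc.b"]]
  probs <- softmax_vec(logits)
  caches$tail_spatial <- sp
  caches$feat <- feat
  caches$probs <- probs
  list(probs = probs, caches = caches)
}

tail_backward <- function(net, dlogits, tl, grads) {
  grads[["fc.W"]] <- (grads[["fc.W"]] %||% 0) +
    tcrossprod(tl$caches$feat, dlogits)
  grads[["fc.b"]] <- (grads[["fc.b"]] %||% 0) + dlogits
  dfeat <- as.numeric(net$params[["fc.W"]] %*% dlogits)
  sp <- tl$caches$tail_spatial
  n_sp <- prod(sp[1:3])
  dx <- array(rep(dfeat / n_sp, each = n_sp), dim = sp)
  ci <- length(tl$caches$blocks)
  ns <- length(net$arch$stages)
  for (s in rev(seq.int(net$config$attention_stage + 1L, ns))) {
    for (b in rev(seq_along(net$arch$stages[[s]]))) {
      bb <- block_backward(dx, net$arch$stages[[s]][[b]], net$params,
                           tl$caches$blocks[[ci]], grads)
      dx <- bb$dx
      grads <- bb$grads
      ci <- ci - 1L
    }
  }
  list(dF = matrix(dx, prod(dim(dx)[1:3]), dim(dx)[4]), grads = grads)
}
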