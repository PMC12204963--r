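# Focal-loss training of the 3-, 2- and 4-class models on synthetic exams.

#' Focal loss for one probability vector
#'
#' `-(1 - p_t)^gamma * log(p_t)` where `p_t` is the probability assigned to
#' the target class; reduces to cross-entropy at `gamma = 0`. `p_t` is
#' clamped below by `eps` so the loss stays finite.
#'
#' @param probs Probability vector (sums to 1 within 1e-6).
#' @param target_class Target index (or class name if `probs` is named).
#' @param gamma Focusing parameter (>= 0).
#' @param eps Clamp for `p_t`.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(probs, target_class, gamma = 2, eps = 1e-7) {
  assert_that(abs(sum(probs) - 1) <= 1e-6, "`probs` must sum to 1")
  if (is.character(target_class)) target_class <- match(target_class, names(probs))
  assert_that(is_count(target_class) && target_class >= 1 &&
                target_class <= length(probs), "invalid target class")
  p_t <- max(probs[[target_class]], eps)
  -(1 - p_t)^gamma * log(p_t)
}

# gradient of the per-phase focal loss w.r.t. the logits
focal_dlogits <- function(probs, target_class, gamma = 2, eps = 1e-7) {
  p_t <- max(probs[[target_class]], eps)
  dp <- numeric(length(probs))
  dp[target_class] <- gamma * (1 - p_t)^(gamma - 1) * log(p_t) -
    (1 - p_t)^gamma / p_t
  softmax_vec_backward(dp, probs)
}

#' Training configuration
#'
#' The `"full"` preset is the full-scale schedule (1000 epochs, Adam at
#' 1e-5, learning rate divided by 10 every 100 epochs, focal loss); the
#' `"desk"` preset is the CPU-scale schedule used throughout the tests
#' (30 epochs at 1e-3, no decay step reached).
#'
#' @param preset `"desk"`, `"full"`, or `NULL`.
#' @param epochs Number of epochs (>= 1).
#' @param base_lr Initial Adam learning rate.
#' @param lr_decay_every Epochs between learning-rate decays.
#' @param lr_decay_factor Division factor at each decay (> 1 divides).
#' @param focal_gamma Focal-loss focusing parameter.
#' @param batch_size Examinations per optimiser step.
#' @param seed Integer seed driving shuffling, augmentation and the split.
#' @param augment_flip,augment_drop,augment_shuffle Augmentation switches:
#'   random flips (shared across an exam's phases), missing-phase
#'   simulation, random phase order.
#' @param val_fraction Held-out validation fraction (stratified by phase-set
#'   composition).
#' @return A list of class `train_config`.
#' @export
train_config <- function(preset = "desk", epochs = NULL, base_lr = NULL,
                         lr_decay_every = 100L, lr_decay_factor = 10,
                         focal_gamma = 2, batch_size = 1L, seed = 1L,
                         augment_flip = TRUE, augment_drop = TRUE,
                         augment_shuffle = TRUE, val_fraction = 0.2) {
  defaults <- switch(preset %||% "custom",
                     desk = list(epochs = 30L, base_lr = 1e-3),
                     full = list(epochs = 1000L, base_lr = 1e-5),
                     custom = list(epochs = 30L, base_lr = 1e-3))
  cfg <- list(epochs = as.integer(epochs %||% defaults$epochs),
              base_lr = base_lr %||% defaults$base_lr,
              lr_decay_every = as.integer(lr_decay_every),
              lr_decay_factor = lr_decay_factor,
              focal_gamma = focal_gamma, batch_size = as.integer(batch_size),
              seed = as.integer(seed), augment_flip = isTRUE(augment_flip),
              augment_drop = isTRUE(augment_drop),
              augment_shuffle = isTRUE(augment_shuffle),
              val_fraction = val_fraction)
  assert_that(cfg$epochs >= 1, "epochs must be >= 1")
  assert_that(cfg$base_lr > 0, "base_lr must be positive")
  assert_that(cfg$lr_decay_every >= 1, "lr_decay_every must be >= 1")
  assert_that(cfg$val_fraction >= 0 && cfg$val_fraction < 1,
              "val_fraction must be in [0, 1)")
  structure(cfg, class = "train_config")
}

#' Learning rate at a (0-based) epoch
#'
#' Step schedule: `base_lr / decay_factor^floor(epoch / decay_every)`.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < cfg$epochs`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  assert_that(all(epoch >= 0 & epoch < cfg$epochs),
              "epoch out of range for this schedule")
  cfg$base_lr * cfg$lr_decay_factor^(-(epoch %/% cfg$lr_decay_every))
}

#' Best validation epoch
#'
#' @param history Training history tibble with a `val_accuracy` column.
#' @return 1-based index of the highest validation accuracy (earliest on
#'   ties).
#' @export
select_best_epoch <- function(history) {
  assert_that(nrow(history) >= 1, "empty history")
  which.max(history$val_accuracy)
}

adam_init <- function(params) {
  list(t = 0L, m = map(params, function(p) p * 0),
       v = map(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# per-model-kind targets for an exam's phases, NA where out of class set
phase_targets <- function(labels, classes) {
  if (length(classes) == 3) match(as_step1(labels), classes)
  else match(labels, classes)
}

#' Train a phase-classification model
#'
#' Trains a [phase_net()] on labelled examinations with focal loss, Adam and
#' the step learning-rate schedule, tracking validation accuracy per epoch
#' and keeping the parameters of the best validation epoch. The class set of
#' `net_cfg` decides the task: 3 classes (AP/PVP/DP) trains the step-1 model
#' on whole exams; 2 classes (EAP/LAP) trains the arterial sub-classifier on
#' single arterial volumes; 4 classes trains the one-step model.
#'
#' @param exams List of labelled [examination()]s (raw HU; they are window
#'   normalized and resampled to the network input internally).
#' @param net_cfg A [net_config()].
#' @param cfg A [train_config()].
#' @param window_level,window_width HU window for preprocessing.
#' @return An object of class `phase_model`: the trained network (best
#'   validation epoch), the training history, and the configurations.
#' @export
train_model <- function(exams, net_cfg = net_config("desk"),
                        cfg = train_config("desk"),
                        window_level = 50, window_width = 600) {
  assert_that(length(exams) >= 1, "empty training set")
  classes <- net_cfg$classes
  # preprocess once; restrict to arterial volumes for the 2-class model
  samples <- map(exams, function(ex) {
    ex <- preprocess_exam(ex, net_cfg$input_shape, window_level, window_width)
    if (length(classes) == 2) {
      keep <- which(true_phases(ex) %in% PHASES_AP)
      if (length(keep) == 0) return(NULL)
      ex$phases <- ex$phases[keep[1]]
    }
    tg <- phase_targets(true_phases(ex), classes)
    if (anyNA(tg)) return(NULL)
    list(exam = ex, targets = tg)
  })
  samples <- samples[!map_lgl(samples, is.null)]
  assert_that(length(samples) >= 1, "no usable training samples for this class set")
  seen <- sort(unique(unlist(map(samples, "targets"))))
  missing <- setdiff(seq_along(classes), seen)
  assert_that(length(missing) == 0,
              paste0("class absent from training data: ",
                     paste(classes[missing], collapse = ", ")))

  # stratified train/validation split by phase-set composition
  strata <- map_chr(samples, function(s) paste(sort(s$targets), collapse = "-"))
  val_idx <- integer(0)
  if (cfg$val_fraction > 0 && length(samples) >= 2) {
    val_idx <- with_seed(derive_seed(cfg$seed, "split"), {
      unlist(map(unique(strata), function(st) {
        idx <- which(strata == st)
        k <- max(if (length(idx) >= 2) 1L else 0L,
                 round(cfg$val_fraction * length(idx)))
        if (k > 0) sample(idx, k) else integer(0)
      }))
    })
  }
  train_idx <- setdiff(seq_along(samples), val_idx)
  assert_that(length(train_idx) >= 1, "validation split left no training samples")

  net <- phase_net(net_cfg, seed = derive_seed(cfg$seed, "net"))
  opt <- adam_init(net$params)
  history <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, params = net$params, epoch = 1L)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(epoch - 1L, cfg)
    order_ep <- with_seed(derive_seed(cfg$seed, paste0("order", epoch)),
                          sample(length(train_idx)))
    losses <- numeric(0)
    batch_grads <- NULL
    batch_n <- 0L
    for (j in seq_along(order_ep)) {
      s <- samples[[train_idx[order_ep[j]]]]
      aug_seed <- derive_seed(cfg$seed, paste0("aug", epoch, "_", j))
      ex <- s$exam
      tg <- s$targets
      if (cfg$augment_drop && length(ex$phases) > 1) {
        keep_before <- length(ex$phases)
        ex <- drop_phases(ex, derive_seed(aug_seed, "d"))
        kept <- match(map_chr(ex$phases, function(p) p$true_phase),
                      map_chr(s$exam$phases, function(p) p$true_phase))
        tg <- s$targets[kept]
      }
      if (cfg$augment_shuffle && length(ex$phases) > 1) {
        perm <- with_seed(derive_seed(aug_seed, "s"), sample(length(ex$phases)))
        ex$phases <- ex$phases[perm]
        tg <- tg[perm]
      }
      if (cfg$augment_flip) ex <- augment_flip_exam(ex, derive_seed(aug_seed, "f"))
      fw <- forward_exam(ex, net, keep_tape = TRUE)
      nph <- nrow(fw$probs)
      dl <- matrix(0, nph, length(classes))
      loss_ex <- 0
      for (p in seq_len(nph)) {
        loss_ex <- loss_ex + focal_loss(fw$probs[p, ], tg[p], cfg$focal_gamma)
        dl[p, ] <- focal_dlogits(fw$probs[p, ], tg[p], cfg$focal_gamma) / nph
      }
      losses <- c(losses, loss_ex / nph)
      g <- backward_exam(net, fw$tape, dl)
      if (is.null(batch_grads)) {
        batch_grads <- g
      } else {
        for (nm in names(g)) batch_grads[[nm]] <- batch_grads[[nm]] + g[[nm]]
      }
      batch_n <- batch_n + 1L
      if (batch_n == cfg$batch_size || j == length(order_ep)) {
        if (batch_n > 1) {
          for (nm in names(batch_grads)) {
            batch_grads[[nm]] <- batch_grads[[nm]] / batch_n
          }
        }
        st <- adam_step(net$params, batch_grads, opt, lr)
        net$params <- st$params
        opt <- st$state
        batch_grads <- NULL
        batch_n <- 0L
      }
    }
    val_acc <- if (length(val_idx) > 0) {
      eval_accuracy(net, samples[val_idx])
    } else {
      eval_accuracy(net, samples[train_idx])
    }
    history[[epoch]] <- tibble(epoch = epoch, loss = mean(losses),
                               val_accuracy = val_acc, lr = lr)
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, params = net$params, epoch = epoch)
    }
  }
  history <- bind_rows(history)
  net$params <- best$params
  structure(
    list(net = net, classes = classes, history = history,
         best_epoch = best$epoch, train_config = cfg, net_config = net_cfg,
         window = c(level = window_level, width = window_width),
         n_train = length(train_idx), n_val = length(val_idx)),
    class = "phase_model"
  )
}

eval_accuracy <- function(net, samples) {
  hits <- 0L
  tot <- 0L
  for (s in samples) {
    probs <- forward_exam(s$exam, net)
    pred <- apply(probs, 1, which.max)
    hits <- hits + sum(pred == s$targets)
    tot <- tot + length(s$targets)
  }
  hits / tot
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf(
    "<phase_model> %d-class (%s), best epoch %d/%d, val accuracy %.3f (n_train %d, n_val %d)\n",
    length(x$classes), paste(x$classes, collapse = ", "), x$best_epoch,
    nrow(x$history), max(x$history$val_accuracy), x$n_train, x$n_val))
  invisible(x)
}

#' @describeIn train_model Per-epoch history as a tibble.
#' @param x A `phase_model`.
#' @param ... Unused.
#' @export
tidy.phase_model <- function(x, ...) x$history

#' @describeIn train_model One-row model summary.
#' @export
glance.phase_model <- function(x, ...) {
  tibble(n_classes = length(x$classes), epochs = nrow(x$history),
         best_epoch = x$best_epoch,
         best_val_accuracy = max(x$history$val_accuracy),
         final_loss = x$history$loss[nrow(x$history)],
         n_parameters = n_params(x$net),
         n_train = x$n_train, n_val = x$n_val)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the network and training configurations alongside
#' the parameters so a model is reconstructable from the file alone.
#'
#' @param model A `phase_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `phase_model`.
#' @export
save_checkpoint <- function(model, path) {
  assert_that(inherits(model, "phase_model"), "not a phase_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  assert_that(inherits(model, "phase_model"), "checkpoint does not hold a phase_model")
  model
}
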