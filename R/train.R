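#' Training configuration
#'
#' @param steps Number of optimization steps (one random crop per step).
#' @param lr Adam learning rate.
#' @param beta1,beta2,eps Adam moment coefficients and stabilizer.
#' @param crop `c(frames, rows, cols)` of the random spatiotemporal crop;
#'   spatial dims must be divisible by the network's downsampling factor.
#'   `NULL` trains on full volumes.
#' @param augment_flips Randomly flip the spatial axes of each crop.
#' @param augment_swap Randomly swap the two inputs each step (on top of
#'   the symmetrized loss).
#' @param val_every Record validation loss every this many steps.
#' @param lr_decay_at Steps after which the learning rate is multiplied
#'   by `lr_decay_factor` (a simple step-decay schedule).
#' @param lr_decay_factor Multiplicative decay applied at each milestone.
#' @param seed RNG seed for initialization, sampling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(steps = 400, lr = 2e-4, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, crop = c(8, 32, 32),
                         augment_flips = TRUE, augment_swap = TRUE,
                         val_every = 50, lr_decay_at = integer(),
                         lr_decay_factor = 0.3, seed = 1) {
  if (lr <= 0) stop("train_config: learning rate must be positive")
  if (steps < 1) stop("train_config: steps must be >= 1")
  structure(list(steps = as.integer(steps), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, crop = crop,
                 augment_flips = isTRUE(augment_flips),
                 augment_swap = isTRUE(augment_swap),
                 val_every = as.integer(val_every),
                 lr_decay_at = as.integer(lr_decay_at),
                 lr_decay_factor = lr_decay_factor,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build (input, input, label) training samples from rendered sets
#'
#' Each [phase_cycled_set()] contributes one sample: its two phase-cycled
#' movies as inputs and either the clean rendered reference or the SPC
#' combination of rendered movies as the label.  Inputs and label are
#' jointly normalized by the shared 99th-percentile factor of the input
#' pair.
#'
#' @param sets List of [phase_cycled_set()]s with exactly two movies each
#'   (label `"reference"`) or at least the SPC increments (label
#'   `"spc"`).
#' @param label `"reference"` (default) or `"spc"`.
#' @return List of samples, each a list of arrays `p1`, `p2`, `label`.
#' @export
make_training_samples <- function(sets, label = c("reference", "spc")) {
  label <- match.arg(label)
  lapply(sets, function(s) {
    stopifnot(inherits(s, "phase_cycled_set"))
    if (label == "reference") {
      if (is.null(s$reference)) stop("make_training_samples: set lacks a reference")
      lab <- s$reference
      inputs <- s$movies[1:2]
    } else {
      lab <- spc_label(s$movies[as.character(c(120, 150, 180, 210, 240))])
      psis <- as.numeric(names(s$movies))
      # opposite-phase pair for the input
      i <- which(((psis[1] + 180) %% 360) == (psis %% 360))
      inputs <- list(s$movies[[1]], s$movies[[i[1]]])
    }
    nz <- normalize_pair(inputs[[1]]$data, inputs[[2]]$data)
    list(p1 = nz$p1, p2 = nz$p2, label = lab$data / nz$scale)
  })
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(model, state, grads, cfg, t) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  lr <- cfg$lr * cfg$lr_decay_factor^sum(t > cfg$lr_decay_at)
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$mW <- b1 * st$mW + (1 - b1) * g$W
    st$vW <- b2 * st$vW + (1 - b2) * g$W^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    model$params[[nm]]$W <- model$params[[nm]]$W -
      lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + cfg$eps)
    model$params[[nm]]$b <- model$params[[nm]]$b -
      lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + cfg$eps)
    state[[nm]] <- st
  }
  list(model = model, state = state)
}

random_crop <- function(sample, crop) {
  d <- dim(sample$p1)
  if (is.null(crop)) return(sample)
  crop <- pmin(crop, d)
  f0 <- sample.int(d[1] - crop[1] + 1, 1) - 1
  y0 <- sample.int(d[2] - crop[2] + 1, 1) - 1
  x0 <- sample.int(d[3] - crop[3] + 1, 1) - 1
  fi <- f0 + seq_len(crop[1]); yi <- y0 + seq_len(crop[2])
  xi <- x0 + seq_len(crop[3])
  list(p1 = sample$p1[fi, yi, xi, drop = FALSE],
       p2 = sample$p2[fi, yi, xi, drop = FALSE],
       label = sample$label[fi, yi, xi, drop = FALSE])
}

flip_sample <- function(sample) {
  for (ax in 2:3) {
    if (runif(1) < 0.5) {
      idx <- rev(seq_len(dim(sample$p1)[ax]))
      sample$p1 <- if (ax == 2) sample$p1[, idx, , drop = FALSE] else
        sample$p1[, , idx, drop = FALSE]
      sample$p2 <- if (ax == 2) sample$p2[, idx, , drop = FALSE] else
        sample$p2[, , idx, drop = FALSE]
      sample$label <- if (ax == 2) sample$label[, idx, , drop = FALSE] else
        sample$label[, , idx, drop = FALSE]
    }
  }
  sample
}

# symmetrized mean-absolute-error loss and parameter gradients for one
# sample; returns loss value and accumulates into `grads`
sym_loss_and_grads <- function(model, sample, grads) {
  shape <- dim(sample$p1)
  x1 <- vol_to_mat(sample$p1); x2 <- vol_to_mat(sample$p2)
  lab <- as.vector(sample$label)
  fa <- net_forward(model, x1, x2, shape, want_cache = TRUE)
  fb <- net_forward(model, x2, x1, shape, want_cache = TRUE)
  out <- (fa$out + fb$out) / 2
  resid <- as.vector(out) - lab
  loss <- mean(abs(resid))
  d <- matrix(sign(resid) / length(resid), ncol = 1)
  net_backward(model, fa$cache, d / 2, grads)
  net_backward(model, fb$cache, d / 2, grads)
  loss
}

# full-volume symmetrized validation loss (no gradients)
validation_loss <- function(model, samples) {
  mean(vapply(samples, function(s) {
    out <- net_apply_sym(model, s$p1, s$p2)
    mean(abs(out - s$label))
  }, numeric(1)))
}

#' Train the dual-encoder network
#'
#' Seeded mini-batch optimization (Adam, one random crop per step) of
#' the mean absolute error between the symmetrized output and the label.
#' The input pair order is additionally randomized per step, augmenting
#' the built-in order symmetry.  Training aborts with a diagnostic if
#' the loss turns non-finite.
#'
#' @param model A `pc_net` from [build_network()].
#' @param samples Training samples from [make_training_samples()].
#' @param cfg A [train_config()].
#' @param val_samples Optional held-out samples for validation loss.
#' @return The trained model; its `history` element is a data frame of
#'   per-step training loss and periodic validation loss.
#' @export
train_network <- function(model, samples, cfg = train_config(),
                          val_samples = NULL) {
  stopifnot(inherits(model, "pc_net"), inherits(cfg, "train_config"))
  if (!length(samples)) stop("train_network: empty dataset")
  for (s in samples)
    if (!identical(dim(s$p1), dim(s$label)))
      stop("train_network: sample/label geometry mismatch")
  set.seed(cfg$seed)
  state <- adam_init(model$params)
  hist_step <- integer(); hist_train <- numeric()
  hist_val_step <- integer(); hist_val <- numeric()
  for (t in seq_len(cfg$steps)) {
    s <- samples[[sample.int(length(samples), 1)]]
    s <- random_crop(s, cfg$crop)
    if (cfg$augment_flips) s <- flip_sample(s)
    if (cfg$augment_swap && runif(1) < 0.5) {
      tmp <- s$p1; s$p1 <- s$p2; s$p2 <- tmp
    }
    grads <- new.env(parent = emptyenv())
    loss <- sym_loss_and_grads(model, s, grads)
    if (!is.finite(loss))
      stop("train_network: non-finite loss at step ", t,
           " (lr too high or degenerate data)")
    upd <- adam_step(model, state, as.list(grads), cfg, t)
    model <- upd$model; state <- upd$state
    hist_step <- c(hist_step, t); hist_train <- c(hist_train, loss)
    if (!is.null(val_samples) && (t %% cfg$val_every == 0 || t == cfg$steps)) {
      hist_val_step <- c(hist_val_step, t)
      hist_val <- c(hist_val, validation_loss(model, val_samples))
    }
  }
  model$train_config <- cfg
  model$history <- list(
    train = data.frame(step = hist_step, loss = hist_train),
    validation = data.frame(step = hist_val_step, loss = hist_val))
  model
}
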