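#' Configuration of the dual-encoder 2D+time network
#'
#' A U-Net-style 2D+time convolutional network with two weight-sharing
#' encoder branches (one per phase-cycled movie) whose feature maps are
#' fused by channel concatenation at every level, a shared decoder, and
#' a residual head: the output is the two-point average `(p1 + p2) / 2`
#' plus a learned correction whose final 1x1x1 layer is zero-initialized,
#' so the untrained network reproduces the averaging baseline exactly.
#' All convolutions are 3x3 spatial x 3 temporal; downsampling halves the
#' spatial axes only, the temporal axis is never downsampled.
#'
#' @param n_levels Number of resolution levels (>= 2).
#' @param base_channels Channels at the full-resolution level; doubled at
#'   each coarser level.
#' @return An object of class `net_config`.
#' @export
net_config <- function(n_levels = 3, base_channels = 8) {
  if (n_levels < 2) stop("net_config: n_levels must be >= 2")
  if (base_channels < 1) stop("net_config: base_channels must be >= 1")
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 channels = as.integer(base_channels * 2^(seq_len(n_levels) - 1))),
            class = "net_config")
}

# layer table: name, cin, cout, kernel taps (27 or 1)
net_layers <- function(cfg) {
  L <- cfg$n_levels; ch <- cfg$channels
  layers <- list()
  for (l in seq_len(L)) {
    cin <- if (l == 1) 1L else ch[l - 1]
    layers[[paste0("enc", l, "a")]] <- list(cin = cin, cout = ch[l], k = 27L)
    layers[[paste0("enc", l, "b")]] <- list(cin = ch[l], cout = ch[l], k = 27L)
  }
  layers[[paste0("dec", L, "a")]] <- list(cin = 2L * ch[L], cout = ch[L],
                                          k = 27L)
  layers[[paste0("dec", L, "b")]] <- list(cin = ch[L], cout = ch[L], k = 27L)
  for (l in rev(seq_len(L - 1))) {
    layers[[paste0("dec", l, "a")]] <- list(cin = ch[l + 1] + 2L * ch[l],
                                            cout = ch[l], k = 27L)
    layers[[paste0("dec", l, "b")]] <- list(cin = ch[l], cout = ch[l], k = 27L)
  }
  layers[["head"]] <- list(cin = ch[1], cout = 1L, k = 1L)
  layers
}

#' Build the dual-encoder network
#'
#' Instantiates the model parameters.  Weight sharing between the two
#' encoder branches is structural: there is a single set of encoder
#' parameters which both branches reference, so the parameter count is
#' independent of which branch an input enters.  The residual head is
#' zero-initialized, making the untrained output exactly the two-point
#' average of the inputs.
#'
#' @param config A [net_config()].
#' @param seed Optional RNG seed for the weight initialization.
#' @return An object of class `pc_net`.
#' @examples
#' m <- build_network(net_config(n_levels = 2, base_channels = 4))
#' n_parameters(m)
#' @export
build_network <- function(config = net_config(), seed = NULL) {
  stopifnot(inherits(config, "net_config"))
  if (!is.null(seed)) set.seed(seed)
  layers <- net_layers(config)
  params <- lapply(names(layers), function(nm) {
    ly <- layers[[nm]]
    fan_in <- ly$k * ly$cin
    W <- if (nm == "head") matrix(0, fan_in, ly$cout) else
      matrix(rnorm(fan_in * ly$cout, sd = sqrt(2 / fan_in)), fan_in, ly$cout)
    list(W = W, b = rep(0, ly$cout))
  })
  names(params) <- names(layers)
  structure(list(config = config, layers = layers, params = params),
            class = "pc_net")
}

#' Number of trainable parameters
#' @param model A [pc_net()] model from [build_network()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.pc_net <- function(x, ...) {
  cat(sprintf("dual-encoder 2D+time network: %d levels, channels %s, %d parameters\n",
              x$config$n_levels, paste(x$config$channels, collapse = "/"),
              n_parameters(x)))
  invisible(x)
}

# one encoder branch; x is an nvox x 1 matrix, shapes the per-level grids
encoder_fwd <- function(model, x, shapes) {
  L <- model$config$n_levels
  feats <- vector("list", L); cache <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    if (l > 1) a <- pool_fwd(a, shapes[[l - 1]])
    c1 <- conv_layer_fwd(a, shapes[[l]], model$params[[paste0("enc", l, "a")]])
    r1 <- relu_fwd(c1$Y)
    c2 <- conv_layer_fwd(r1$A, shapes[[l]],
                         model$params[[paste0("enc", l, "b")]])
    r2 <- relu_fwd(c2$Y)
    feats[[l]] <- r2$A
    cache[[l]] <- list(P1 = c1$P, M1 = r1$M, P2 = c2$P, M2 = r2$M)
    a <- r2$A
  }
  list(feats = feats, cache = cache)
}

encoder_bwd <- function(model, cache, dfeats, shapes, grads) {
  L <- model$config$n_levels
  ch <- model$config$channels
  g_above <- NULL
  for (l in rev(seq_len(L))) {
    g <- dfeats[[l]]
    if (!is.null(g_above)) g <- g + pool_bwd(g_above, shapes[[l]])
    cc <- cache[[l]]
    dz2 <- g * cc$M2
    b2 <- conv_layer_bwd(cc$P2, model$params[[paste0("enc", l, "b")]], dz2,
                         shapes[[l]], ch[l])
    acc_grad(grads, paste0("enc", l, "b"), b2)
    dz1 <- b2$dX * cc$M1
    cin <- if (l == 1) 1L else ch[l - 1]
    b1 <- conv_layer_bwd(cc$P1, model$params[[paste0("enc", l, "a")]], dz1,
                         shapes[[l]], cin)
    acc_grad(grads, paste0("enc", l, "a"), b1)
    g_above <- if (l > 1) b1$dX else NULL
  }
  invisible(NULL)
}

acc_grad <- function(grads, nm, b) {
  if (is.null(grads[[nm]])) {
    grads[[nm]] <- list(W = b$dW, b = as.vector(b$db))
  } else {
    grads[[nm]]$W <- grads[[nm]]$W + b$dW
    grads[[nm]]$b <- grads[[nm]]$b + as.vector(b$db)
  }
}

level_shapes <- function(cfg, shape) {
  L <- cfg$n_levels
  mult <- 2^(L - 1)
  if (shape[2] %% mult || shape[3] %% mult)
    stop("spatial dims must be divisible by ", mult)
  lapply(seq_len(L), function(l) c(shape[1], shape[2] %/% 2^(l - 1),
                                   shape[3] %/% 2^(l - 1)))
}

# full forward pass on normalized nvox x 1 inputs; returns output and,
# if wanted, the cache needed for backprop
net_forward <- function(model, x1, x2, shape, want_cache = FALSE) {
  cfg <- model$config
  L <- cfg$n_levels
  shapes <- level_shapes(cfg, shape)
  e1 <- encoder_fwd(model, x1, shapes)
  e2 <- encoder_fwd(model, x2, shapes)
  dec <- vector("list", L); dcache <- vector("list", L)
  cat_in <- cbind(e1$feats[[L]], e2$feats[[L]])
  c1 <- conv_layer_fwd(cat_in, shapes[[L]], model$params[[paste0("dec", L, "a")]])
  r1 <- relu_fwd(c1$Y)
  c2 <- conv_layer_fwd(r1$A, shapes[[L]], model$params[[paste0("dec", L, "b")]])
  r2 <- relu_fwd(c2$Y)
  dec[[L]] <- r2$A
  dcache[[L]] <- list(P1 = c1$P, M1 = r1$M, P2 = c2$P, M2 = r2$M)
  for (l in rev(seq_len(L - 1))) {
    u <- upsample_fwd(dec[[l + 1]], shapes[[l + 1]])
    cat_in <- cbind(u, e1$feats[[l]], e2$feats[[l]])
    c1 <- conv_layer_fwd(cat_in, shapes[[l]],
                         model$params[[paste0("dec", l, "a")]])
    r1 <- relu_fwd(c1$Y)
    c2 <- conv_layer_fwd(r1$A, shapes[[l]],
                         model$params[[paste0("dec", l, "b")]])
    r2 <- relu_fwd(c2$Y)
    dec[[l]] <- r2$A
    dcache[[l]] <- list(P1 = c1$P, M1 = r1$M, P2 = c2$P, M2 = r2$M)
  }
  hc <- conv_layer_fwd(dec[[1]], shapes[[1]], model$params$head, kernel = 1L)
  base <- (x1 + x2) / 2
  pre <- base + hc$Y
  out <- pmax(pre, 0)
  if (!want_cache) return(list(out = out))
  list(out = out, cache = list(e1 = e1, e2 = e2, dcache = dcache,
                               headP = hc$P, pre = pre, shapes = shapes))
}

# backward pass accumulating parameter gradients into the environment
# `grads`; dOut is the loss gradient w.r.t. the clamped output
net_backward <- function(model, cache, dOut, grads) {
  cfg <- model$config
  L <- cfg$n_levels
  ch <- cfg$channels
  shapes <- cache$shapes
  dpre <- dOut * (cache$pre > 0)
  bh <- conv_layer_bwd(cache$headP, model$params$head, dpre, shapes[[1]],
                       ch[1], kernel = 1L)
  acc_grad(grads, "head", bh)
  df1 <- vector("list", L); df2 <- vector("list", L)
  ddec <- vector("list", L)
  ddec[[1]] <- bh$dX
  for (l in seq_len(L - 1)) {
    cc <- cache$dcache[[l]]
    dz2 <- ddec[[l]] * cc$M2
    b2 <- conv_layer_bwd(cc$P2, model$params[[paste0("dec", l, "b")]], dz2,
                         shapes[[l]], ch[l])
    acc_grad(grads, paste0("dec", l, "b"), b2)
    dz1 <- b2$dX * cc$M1
    cin <- ch[l + 1] + 2L * ch[l]
    b1 <- conv_layer_bwd(cc$P1, model$params[[paste0("dec", l, "a")]], dz1,
                         shapes[[l]], cin)
    acc_grad(grads, paste0("dec", l, "a"), b1)
    dcat <- b1$dX
    du <- dcat[, seq_len(ch[l + 1]), drop = FALSE]
    df1[[l]] <- dcat[, ch[l + 1] + seq_len(ch[l]), drop = FALSE]
    df2[[l]] <- dcat[, ch[l + 1] + ch[l] + seq_len(ch[l]), drop = FALSE]
    up_grad <- upsample_bwd(du, shapes[[l + 1]])
    ddec[[l + 1]] <- if (is.null(ddec[[l + 1]])) up_grad else
      ddec[[l + 1]] + up_grad
  }
  cc <- cache$dcache[[L]]
  dz2 <- ddec[[L]] * cc$M2
  b2 <- conv_layer_bwd(cc$P2, model$params[[paste0("dec", L, "b")]], dz2,
                       shapes[[L]], ch[L])
  acc_grad(grads, paste0("dec", L, "b"), b2)
  dz1 <- b2$dX * cc$M1
  b1 <- conv_layer_bwd(cc$P1, model$params[[paste0("dec", L, "a")]], dz1,
                       shapes[[L]], 2L * ch[L])
  acc_grad(grads, paste0("dec", L, "a"), b1)
  dcat <- b1$dX
  df1[[L]] <- dcat[, seq_len(ch[L]), drop = FALSE]
  df2[[L]] <- dcat[, ch[L] + seq_len(ch[L]), drop = FALSE]
  encoder_bwd(model, cache$e1$cache, df1, shapes, grads)
  encoder_bwd(model, cache$e2$cache, df2, shapes, grads)
  invisible(NULL)
}

#' Shared-scale normalization of a phase-cycled pair
#'
#' Divides both movies by one shared factor -- the 99th percentile of
#' their pooled voxel values -- so the inter-movie intensity relationship
#' that encodes banding is preserved.  All-zero inputs are returned
#' unchanged with factor 1 and a warning.
#'
#' @param p1,p2 Non-negative arrays or [cine_movie()]s.
#' @return A list with `p1`, `p2` (scaled, same type as the input) and
#'   `scale`.
#' @export
normalize_pair <- function(p1, p2) {
  a1 <- if (inherits(p1, "cine_movie")) p1$data else p1
  a2 <- if (inherits(p2, "cine_movie")) p2$data else p2
  f <- as.numeric(quantile(c(a1, a2), 0.99))
  if (!is.finite(f) || f <= 0) {
    warning("normalize_pair: all-zero input; factor 1 used")
    return(list(p1 = p1, p2 = p2, scale = 1))
  }
  scale_one <- function(p, a) {
    if (inherits(p, "cine_movie")) { p$data <- a / f; p } else a / f
  }
  list(p1 = scale_one(p1, a1), p2 = scale_one(p2, a2), scale = f)
}

# run the padded, normalized forward for both input orders and average
net_apply_sym <- function(model, a1, a2) {
  mult <- 2^(model$config$n_levels - 1)
  pd <- pad_to_multiple(a1, mult)
  a1p <- pd$arr; a2p <- pad_to_multiple(a2, mult)$arr
  shape <- dim(a1p)
  x1 <- vol_to_mat(a1p); x2 <- vol_to_mat(a2p)
  o12 <- net_forward(model, x1, x2, shape)$out
  o21 <- net_forward(model, x2, x1, shape)$out
  out <- mat_to_vol((o12 + o21) / 2, shape)
  crop_to(out, pd$orig)
}

#' Order-invariant (symmetrized) inference
#'
#' Predicts the artifact-suppressed movie twice with the two input
#' orders and averages the results, so the reconstruction is invariant
#' to the order of the phase-cycled inputs by construction.  Inputs are
#' jointly normalized ([normalize_pair()]), reflectively padded to the
#' network's divisibility requirement, and the output is cropped back,
#' denormalized and clamped to non-negative values.
#'
#' @param model A [pc_net()] from [build_network()] or [train_network()].
#' @param p1,p2 Magnitude [cine_movie()]s (or arrays) with identical
#'   geometry.
#' @return Reconstructed movie of the same type and geometry as `p1`.
#' @export
symmetrized_inference <- function(model, p1, p2) {
  stopifnot(inherits(model, "pc_net"))
  a1 <- if (inherits(p1, "cine_movie")) p1$data else p1
  a2 <- if (inherits(p2, "cine_movie")) p2$data else p2
  if (!identical(dim(a1), dim(a2)))
    stop("symmetrized_inference: geometry mismatch: ",
         paste(dim(a1), collapse = "x"), " vs ", paste(dim(a2), collapse = "x"))
  nz <- normalize_pair(a1, a2)
  out <- net_apply_sym(model, nz$p1, nz$p2) * nz$scale
  out <- pmax(out, 0)
  if (inherits(p1, "cine_movie")) {
    res <- p1
    res$data <- out
    res$psi_deg <- NA_real_
    res$combined_from <- c(p1$psi_deg, p2$psi_deg)
    res$label <- "network"
    res
  } else out
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the network configuration, parameters, the
#' training configuration and seed (when trained), and the loss history.
#'
#' @param model A [pc_net()].
#' @param path Checkpoint file path (RDS).
#' @return `load_checkpoint` returns the model; `save_checkpoint`
#'   invisibly returns `path`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pc_net"))
  atomic_write(path, function(tmp) saveRDS(model, tmp))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pc_net"))
    stop("load_checkpoint: not a pc_net checkpoint: ", path)
  model
}
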