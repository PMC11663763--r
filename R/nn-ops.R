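# Internal primitives for the 2D+time convolutional network.
#
# Feature volumes are (nvox x channels) matrices over a (t, y, x) grid
# with t fastest in the linear voxel order.  Convolutions are 3x3x3
# ("same", zero boundary) realized as a gathered-patch GEMM in C++
# (conv_fwd / conv_bwd); pooling and upsampling act on the spatial axes
# only, so the temporal dimension is never downsampled.

.shape_cache <- new.env(parent = emptyenv())

shape_key <- function(shape) paste(shape, collapse = "x")

# nvox x 27 gather table for a 3x3x3 kernel; 0 = out of bounds
conv_index <- function(shape) {
  key <- paste0("conv_", shape_key(shape))
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  nt <- shape[1]; ny <- shape[2]; nx <- shape[3]
  nvox <- nt * ny * nx
  gt <- rep_len(seq_len(nt), nvox)
  gy <- rep(rep(seq_len(ny), each = nt), nx)
  gx <- rep(seq_len(nx), each = nt * ny)
  idx <- matrix(0L, nvox, 27)
  k <- 0
  for (dx in -1:1) for (dy in -1:1) for (dt in -1:1) {
    k <- k + 1
    ts <- gt + dt; ys <- gy + dy; xs <- gx + dx
    ok <- ts >= 1 & ts <= nt & ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
    id <- integer(nvox)
    id[ok] <- (xs[ok] - 1L) * ny * nt + (ys[ok] - 1L) * nt + ts[ok]
    idx[, k] <- id
  }
  .shape_cache[[key]] <- idx
  idx
}

# 2x2 spatial average pooling tables: 4 source indices per coarse voxel
pool_index <- function(shape) {
  key <- paste0("pool_", shape_key(shape))
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  nt <- shape[1]; ny <- shape[2]; nx <- shape[3]
  stopifnot(ny %% 2 == 0, nx %% 2 == 0)
  nyo <- ny %/% 2; nxo <- nx %/% 2
  nvo <- nt * nyo * nxo
  gt <- rep_len(seq_len(nt), nvo)
  gy <- rep(rep(seq_len(nyo), each = nt), nxo)
  gx <- rep(seq_len(nxo), each = nt * nyo)
  lin <- function(t, y, x) (x - 1L) * ny * nt + (y - 1L) * nt + t
  idx <- cbind(lin(gt, 2L * gy - 1L, 2L * gx - 1L),
               lin(gt, 2L * gy, 2L * gx - 1L),
               lin(gt, 2L * gy - 1L, 2L * gx),
               lin(gt, 2L * gy, 2L * gx))
  out <- list(idx = idx, out_shape = c(nt, nyo, nxo))
  .shape_cache[[key]] <- out
  out
}

pool_fwd <- function(X, shape) {
  p <- pool_index(shape)
  i <- p$idx
  Y <- (X[i[, 1], , drop = FALSE] + X[i[, 2], , drop = FALSE] +
        X[i[, 3], , drop = FALSE] + X[i[, 4], , drop = FALSE]) / 4
  attr(Y, "shape") <- p$out_shape
  Y
}

pool_bwd <- function(dY, shape) {
  p <- pool_index(shape)
  dX <- matrix(0, prod(shape), ncol(dY))
  q <- dY / 4
  for (k in 1:4) dX[p$idx[, k], ] <- dX[p$idx[, k], ] + q
  dX
}

# nearest-neighbour 2x spatial upsampling: fine voxel -> coarse source
upsample_index <- function(coarse_shape) {
  key <- paste0("up_", shape_key(coarse_shape))
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  nt <- coarse_shape[1]; ny <- coarse_shape[2]; nx <- coarse_shape[3]
  nyf <- ny * 2L; nxf <- nx * 2L
  nvf <- nt * nyf * nxf
  gt <- rep_len(seq_len(nt), nvf)
  gy <- rep(rep(seq_len(nyf), each = nt), nxf)
  gx <- rep(seq_len(nxf), each = nt * nyf)
  cy <- (gy + 1L) %/% 2L; cx <- (gx + 1L) %/% 2L
  map <- (cx - 1L) * ny * nt + (cy - 1L) * nt + gt
  out <- list(map = map, out_shape = c(nt, nyf, nxf))
  .shape_cache[[key]] <- out
  out
}

upsample_fwd <- function(X, coarse_shape) {
  u <- upsample_index(coarse_shape)
  Y <- X[u$map, , drop = FALSE]
  attr(Y, "shape") <- u$out_shape
  Y
}

upsample_bwd <- function(dY, coarse_shape) {
  u <- upsample_index(coarse_shape)
  rowsum(dY, u$map)
}

conv_layer_fwd <- function(X, shape, par, kernel = 27L) {
  idx <- if (kernel == 27L) conv_index(shape) else
    matrix(seq_len(nrow(X)), ncol = 1)
  conv_fwd(X, idx, par$W, par$b)
}

conv_layer_bwd <- function(P, par, dY, shape, cin, kernel = 27L) {
  idx <- if (kernel == 27L) conv_index(shape) else
    matrix(seq_len(nrow(dY)), ncol = 1)
  conv_bwd(P, par$W, dY, idx, cin)
}

relu_fwd <- function(Z) {
  M <- Z > 0
  list(A = Z * M, M = M)
}

# volume array (t, y, x) -> nvox x 1 matrix and back
vol_to_mat <- function(arr) {
  m <- matrix(as.vector(arr), ncol = 1)
  attr(m, "shape") <- dim(arr)
  m
}

mat_to_vol <- function(m, shape) array(as.vector(m), shape)

# reflective pad of spatial dims up to a multiple of 2^(n_levels-1);
# returns padded array and the original spatial dims
pad_to_multiple <- function(arr, mult) {
  d <- dim(arr)
  py <- (mult - d[2] %% mult) %% mult
  px <- (mult - d[3] %% mult) %% mult
  if (py == 0 && px == 0) return(list(arr = arr, orig = d))
  refl <- function(n, p) c(seq_len(n), rev(seq_len(n))[seq_len(p) + 1L])
  yi <- refl(d[2], py)
  xi <- refl(d[3], px)
  list(arr = arr[, yi, xi, drop = FALSE], orig = d)
}

crop_to <- function(arr, orig) arr[, seq_len(orig[2]), seq_len(orig[3]),
                                   drop = FALSE]
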