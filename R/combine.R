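#' Voxel-wise average of magnitude cine movies
#'
#' Arithmetic mean of co-registered magnitude movies.  Averaging movies
#' acquired with different RF phase increments flattens the overall bSSFP
#' magnitude response, reducing banding; with the two half-cycle-apart
#' movies of a twofold acquisition this is the classical two-point
#' average baseline.
#'
#' @param movies List of [cine_movie()]s with identical geometry.
#' @return A [cine_movie()] whose `combined_from` records the
#'   contributing psi values.
#' @export
average_combine <- function(movies) {
  if (!length(movies)) stop("average_combine: need at least one movie")
  dims <- lapply(movies, function(m) dim(m$data))
  if (length(unique(dims)) != 1)
    stop("average_combine: geometry mismatch: ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"),
                      character(1)), collapse = " vs "))
  acc <- Reduce(`+`, lapply(movies, function(m) m$data)) / length(movies)
  m1 <- movies[[1]]
  cine_movie(acc, psi_deg = NA, tr_ms = m1$tr_ms, te_ms = m1$te_ms,
             flip_deg = m1$flip_deg, frame_duration_ms = m1$frame_duration_ms,
             combined_from = vapply(movies, function(m) m$psi_deg, numeric(1)),
             label = "average")
}

# temporal mean image of a movie
temporal_mean <- function(movie) apply(movie$data, c(2, 3), mean)

# normalized cross-correlation of the overlap for an integer shift
ncc_at_shift <- function(moving, fixed, dy, dx) {
  ny <- nrow(fixed); nx <- ncol(fixed)
  ys_f <- max(1, 1 + dy):min(ny, ny + dy)
  xs_f <- max(1, 1 + dx):min(nx, nx + dx)
  if (length(ys_f) < 8 || length(xs_f) < 8) return(-Inf)
  a <- fixed[ys_f, xs_f]
  b <- moving[ys_f - dy, xs_f - dx]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(-Inf)
  sum(a * b) / den
}

# quadratic (parabolic) refinement of a discrete maximum
parabolic_peak <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  d <- 0.5 * (ym1 - yp1) / den
  max(min(d, 0.5), -0.5)
}

# bilinear sampling of img at (row, col) coordinates, zero outside
bilinear_sample <- function(img, ys, xs) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    out <- numeric(length(yy))
    out[ok] <- img[cbind(yy[ok], xx[ok])]
    out
  }
  (1 - fy) * (1 - fx) * val(y0, x0) + (1 - fy) * fx * val(y0, x0 + 1) +
    fy * (1 - fx) * val(y0 + 1, x0) + fy * fx * val(y0 + 1, x0 + 1)
}

# apply a rigid transform (rotation about the image center, then
# translation) to one frame by backward warping
warp_frame <- function(img, dy, dx, angle_deg = 0) {
  ny <- nrow(img); nx <- ncol(img)
  Y <- matrix(seq_len(ny), ny, nx)
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  yc <- (ny + 1) / 2; xc <- (nx + 1) / 2
  a <- -angle_deg * pi / 180     # inverse rotation for backward warp
  Ys <- Y - dy; Xs <- X - dx
  if (angle_deg != 0) {
    U <- Ys - yc; V <- Xs - xc
    Ys <- yc + cos(a) * U + sin(a) * V
    Xs <- xc - sin(a) * U + cos(a) * V
  }
  matrix(bilinear_sample(img, as.vector(Ys), as.vector(Xs)), ny, nx)
}

#' Rigid registration of two cine movies
#'
#' Estimates a single in-plane transform (translation, optionally a
#' small rotation) between the temporal-mean images of two movies by
#' maximizing normalized cross-correlation over integer shifts followed
#' by parabolic subpixel refinement, and applies it to every frame of
#' the moving movie with bilinear interpolation.  A single transform per
#' movie is used because the dominant misregistration source between
#' movies is a constant breath-hold offset.
#'
#' @param moving,fixed [cine_movie()]s with identical geometry.
#' @param max_shift_px Integer search radius in pixels.
#' @param rotate If `TRUE`, also search a small rotation grid.
#' @param max_angle_deg Rotation search half-range in degrees.
#' @return A list with `transform` (list of `dy`, `dx`, `angle_deg`,
#'   `degenerate`) and `movie` (the resampled moving movie).  Degenerate
#'   (constant) images yield the identity transform with
#'   `degenerate = TRUE` and a warning.
#' @export
rigid_register <- function(moving, fixed, max_shift_px = 8, rotate = FALSE,
                           max_angle_deg = 5) {
  stopifnot(inherits(moving, "cine_movie"), inherits(fixed, "cine_movie"))
  if (!identical(dim(moving$data), dim(fixed$data)))
    stop("rigid_register: geometry mismatch")
  tm_m <- temporal_mean(moving); tm_f <- temporal_mean(fixed)
  if (sd(tm_m) < 1e-12 * max(1, mean(tm_m)) ||
      sd(tm_f) < 1e-12 * max(1, mean(tm_f))) {
    warning("rigid_register: degenerate (constant) image; identity returned")
    return(list(transform = list(dy = 0, dx = 0, angle_deg = 0,
                                 degenerate = TRUE),
                movie = moving))
  }
  angles <- if (rotate) seq(-max_angle_deg, max_angle_deg, by = 1) else 0
  best <- list(ncc = -Inf)
  r <- as.integer(max_shift_px)
  for (ang in angles) {
    mov <- if (ang == 0) tm_m else warp_frame(tm_m, 0, 0, ang)
    cc <- matrix(-Inf, 2 * r + 1, 2 * r + 1)
    for (dy in -r:r) for (dx in -r:r)
      cc[dy + r + 1, dx + r + 1] <- ncc_at_shift(mov, tm_f, dy, dx)
    ij <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
    dy0 <- ij[1] - r - 1; dx0 <- ij[2] - r - 1
    if (cc[ij[1], ij[2]] > best$ncc)
      best <- list(ncc = cc[ij[1], ij[2]], dy = dy0, dx = dx0, angle = ang,
                   cc = cc, ij = ij)
  }
  if (best$ncc < 0.2) {
    warning("rigid_register: no reliable structure correlation; identity returned")
    return(list(transform = list(dy = 0, dx = 0, angle_deg = 0,
                                 degenerate = TRUE),
                movie = moving))
  }
  # subpixel refinement along each axis
  dy <- best$dy; dx <- best$dx
  i <- best$ij[1]; j <- best$ij[2]; cc <- best$cc
  if (i > 1 && i < nrow(cc) && all(is.finite(cc[(i - 1):(i + 1), j])))
    dy <- dy + parabolic_peak(cc[i - 1, j], cc[i, j], cc[i + 1, j])
  if (j > 1 && j < ncol(cc) && all(is.finite(cc[i, (j - 1):(j + 1)])))
    dx <- dx + parabolic_peak(cc[i, j - 1], cc[i, j], cc[i, j + 1])
  out <- moving$data
  for (f in seq_len(dim(out)[1]))
    out[f, , ] <- pmax(warp_frame(moving$data[f, , ], dy, dx, best$angle), 0)
  res <- moving; res$data <- out
  list(transform = list(dy = dy, dx = dx, angle_deg = best$angle,
                        degenerate = FALSE),
       movie = res)
}

#' Short-range phase-cycling (SPC) label
#'
#' The artifact-suppression training label: the voxel-wise mean of the
#' five movies with RF phase increments 120, 150, 180, 210 and 240
#' degrees, after rigidly registering each movie to the 180-degree movie
#' to remove breath-hold offsets.  The short phase-cycling range balances
#' banding suppression against the incurrence of new flow artifacts.
#'
#' @param movies List of five [cine_movie()]s carrying exactly the
#'   increments 120, 150, 180, 210, 240 (any order).
#' @param ... Passed to [rigid_register()].
#' @return A [cine_movie()] labelled `"spc"`.
#' @export
spc_label <- function(movies, ...) {
  wanted <- c(120, 150, 180, 210, 240)
  psis <- vapply(movies, function(m) m$psi_deg, numeric(1))
  missing_psi <- setdiff(wanted, round(psis))
  extra <- setdiff(round(psis), wanted)
  if (length(missing_psi) || length(extra) || length(movies) != 5)
    stop("spc_label: need exactly psi = {120,150,180,210,240}; missing: {",
         paste(missing_psi, collapse = ","), "}, extra: {",
         paste(extra, collapse = ","), "}")
  fixed <- movies[[which(round(psis) == 180)]]
  aligned <- lapply(movies, function(m) {
    if (round(m$psi_deg) == 180) m else rigid_register(m, fixed, ...)$movie
  })
  out <- average_combine(aligned)
  out$label <- "spc"
  out
}
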