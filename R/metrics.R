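check_roi <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  if (sum(roi$data) < 8)
    stop("ROI too small: metrics need at least 8 foreground pixels")
  invisible(roi)
}

check_same_geom <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("geometry mismatch: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
}

roi_values <- function(movie, roi) {
  nf <- dim(movie$data)[1]
  sel <- which(roi$data)
  vapply(seq_len(nf), function(f) movie$data[f, , ][sel],
         numeric(length(sel)))
}

#' Peak signal-to-noise ratio within an ROI
#'
#' `20 * log10(L / RMSE)` with the root-mean-square error taken over the
#' ROI pixels of all frames and the peak `L` equal to the reference
#' maximum within the ROI.  Identical movies return `Inf`.
#'
#' @param test,ref [cine_movie()]s with identical geometry.
#' @param roi A [roi_mask()] with at least 8 pixels.
#' @return PSNR in decibels.
#' @export
roi_psnr <- function(test, ref, roi) {
  check_same_geom(test, ref); check_roi(roi)
  tv <- roi_values(test, roi); rv <- roi_values(ref, roi)
  rmse <- sqrt(mean((tv - rv)^2))
  if (rmse == 0) return(Inf)
  20 * log10(max(rv) / rmse)
}

# 1D Gaussian smoothing operator (n x n), truncated and row-renormalized
# at the image edges
gauss_op <- function(n, size = 11, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    A[i, j[ok]] <- g[ok]
    A[i, ] <- A[i, ] / sum(A[i, ])
  }
  A
}

#' Structural similarity within an ROI
#'
#' Standard per-frame SSIM with a Gaussian window (11 x 11, sigma 1.5)
#' and stability constants `K1 = 0.01`, `K2 = 0.03`; the dynamic range is
#' the reference maximum within the ROI.  The per-pixel SSIM map is
#' averaged over the ROI pixels of all frames.
#'
#' @inheritParams roi_psnr
#' @param size,sigma Gaussian window size and width.
#' @return SSIM value in \[-1, 1\].
#' @export
roi_ssim <- function(test, ref, roi, size = 11, sigma = 1.5) {
  check_same_geom(test, ref); check_roi(roi)
  d <- dim(ref$data); nf <- d[1]; ny <- d[2]; nx <- d[3]
  L <- max(roi_values(ref, roi))
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  Ay <- gauss_op(ny, size, sigma); Ax <- gauss_op(nx, size, sigma)
  smooth <- function(img) Ay %*% img %*% t(Ax)
  sel <- which(roi$data)
  vals <- vapply(seq_len(nf), function(f) {
    x <- ref$data[f, , ]; y <- test$data[f, , ]
    mx <- smooth(x); my <- smooth(y)
    sxx <- smooth(x * x) - mx^2
    syy <- smooth(y * y) - my^2
    sxy <- smooth(x * y) - mx * my
    ssim_map <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
      ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    mean(ssim_map[sel])
  }, numeric(1))
  mean(vals)
}

#' Coefficient of variation within an ROI
#'
#' Per-frame standard deviation over mean of the ROI pixels, averaged
#' across frames.  A uniformly bright (artifact-free) blood pool has a
#' low COV; banding raises it.
#'
#' @param movie A [cine_movie()].
#' @param roi A [roi_mask()].
#' @return Dimensionless ratio.
#' @export
roi_cov <- function(movie, roi) {
  check_roi(roi)
  v <- roi_values(movie, roi)
  mu <- colMeans(v)
  if (any(mu <= 0)) stop("roi_cov: ROI mean must be positive")
  mean(apply(v, 2, sd) / mu)
}

#' Normalized mean ROI signal
#'
#' Mean ROI signal of a movie divided by the mean ROI signal of a
#' banding-free reference (frames pooled).  Values well below 1 indicate
#' signal dropout (banding) within the ROI.
#'
#' @param movie,ref [cine_movie()]s with identical geometry.
#' @param roi A [roi_mask()].
#' @return Dimensionless ratio.
#' @export
normalized_mean_signal <- function(movie, roi, ref) {
  check_same_geom(movie, ref); check_roi(roi)
  den <- mean(roi_values(ref, roi))
  if (den <= 0) stop("normalized_mean_signal: reference ROI mean must be > 0")
  mean(roi_values(movie, roi)) / den
}

#' Dice overlap of two masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined to overlap
#' perfectly (1.0).
#'
#' @param a,b [roi_mask()]s with identical geometry.
#' @return Value in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("dice_coefficient: geometry mismatch")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}

#' Evaluate reconstructions of a phase-cycled set
#'
#' Computes ROI PSNR and SSIM against the set's artifact-free reference
#' for every input movie and every named reconstruction, plus COV and
#' normalized mean signal for the requested ROIs.
#'
#' @param set A [phase_cycled_set()] with a reference and a `heart` mask.
#' @param methods Named list of reconstructed [cine_movie()]s.
#' @param rois Character vector of mask names used for COV/signal rows;
#'   defaults to all masks large enough for the metrics (>= 8 pixels).
#' @return A data frame with columns `source`, `metric`, `roi`, `value`.
#' @export
evaluate_set <- function(set, methods = list(), rois = NULL) {
  if (is.null(rois))
    rois <- names(set$masks)[vapply(set$masks, function(m)
      sum(m$data) >= 8, logical(1))]
  stopifnot(inherits(set, "phase_cycled_set"))
  if (is.null(set$reference))
    stop("evaluate_set: set has no reference movie")
  if (!"heart" %in% names(set$masks))
    stop("evaluate_set: set has no heart mask")
  heart <- set$masks$heart
  sources <- c(stats::setNames(set$movies,
                               paste0("psi_", names(set$movies))), methods)
  rows <- list()
  add <- function(source, metric, roi, value)
    rows[[length(rows) + 1]] <<- data.frame(source = source, metric = metric,
                                            roi = roi, value = value)
  for (nm in names(sources)) {
    m <- sources[[nm]]
    add(nm, "psnr", "heart", roi_psnr(m, set$reference, heart))
    add(nm, "ssim", "heart", roi_ssim(m, set$reference, heart))
    for (rn in rois) {
      add(nm, "cov", rn, roi_cov(m, set$masks[[rn]]))
      add(nm, "norm_mean_signal", rn,
          normalized_mean_signal(m, set$masks[[rn]], set$reference))
    }
  }
  do.call(rbind, rows)
}

#' Write a metrics table to CSV and/or JSON
#'
#' @param metrics Data frame from [evaluate_set()].
#' @param csv,json Output paths (either may be `NULL`).
#' @return Invisibly, the metrics table.
#' @export
write_metrics <- function(metrics, csv = NULL, json = NULL) {
  if (!is.null(csv))
    atomic_write(csv, function(tmp)
      write.csv(metrics, tmp, row.names = FALSE))
  if (!is.null(json))
    atomic_write(json, function(tmp)
      jsonlite::write_json(metrics, tmp, dataframe = "rows", digits = NA))
  invisible(metrics)
}
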