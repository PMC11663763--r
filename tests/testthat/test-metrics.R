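make_roi <- function(ny = 24, nx = 24, on = 5:20) {
  m <- matrix(FALSE, ny, nx)
  m[on, on] <- TRUE
  roi_mask(m, "heart")
}

test_that("ROI PSNR follows its closed form and scale invariance", {
  roi <- make_roi()
  ref <- cine_movie(array(1, c(2, 24, 24)))
  expect_identical(roi_psnr(ref, ref, roi), Inf)
  test <- ref; test$data <- pmax(ref$data - 0.1, 0)
  expect_equal(roi_psnr(test, ref, roi), 20)
  s_test <- test; s_test$data <- 3 * test$data
  s_ref <- ref; s_ref$data <- 3 * ref$data
  expect_equal(roi_psnr(s_test, s_ref, roi), 20)
  expect_error(roi_psnr(test, ref, make_roi(on = 1:2)), "ROI too small")
  bad <- cine_movie(array(1, c(2, 12, 24)))
  expect_error(roi_psnr(bad, ref, roi), "geometry")
})

test_that("ROI SSIM matches an independent reference implementation", {
  y <- matrix(1:40, 40, 40); x <- matrix(1:40, 40, 40, byrow = TRUE)
  img1 <- 0.5 + 0.4 * sin(x / 3) * cos(y / 5)
  img2 <- img1 * (0.8 + 0.2 * sin((x + y) / 4))
  roi <- matrix(FALSE, 40, 40); roi[7:34, 7:34] <- TRUE
  m1 <- cine_movie(array(img1, c(1, 40, 40)))
  m2 <- cine_movie(array(img2, c(1, 40, 40)))
  # frozen value from scikit-image structural_similarity (gaussian_weights,
  # sigma 1.5, no sample covariance, data_range = ROI max of the reference),
  # averaged over the same interior ROI
  expect_equal(roi_ssim(m2, m1, roi_mask(roi)), 0.8874517, tolerance = 1e-6)
  expect_equal(roi_ssim(m1, m1, roi_mask(roi)), 1.0)
})

test_that("ROI SSIM degrades with noise and structure loss", {
  set.seed(9)
  base <- tiny_lv_set()
  ref <- base$reference; roi <- base$masks$heart
  noisy <- ref
  noisy$data <- pmax(ref$data + array(rnorm(length(ref$data),
                                            sd = 0.1 * max(ref$data)),
                                      dim(ref$data)), 0)
  expect_lt(roi_ssim(noisy, ref, roi), roi_ssim(ref, ref, roi))
  flat <- ref; flat$data[] <- mean(ref$data)
  expect_lt(roi_ssim(flat, ref, roi), 0.2)
})

test_that("COV and normalized mean signal follow hand arithmetic", {
  roi <- make_roi(8, 8, 1:8)
  vals <- array(rep(c(1, 3), each = 32), c(1, 8, 8))
  m <- cine_movie(vals)
  expect_equal(roi_cov(m, roi), sd(rep(c(1, 3), each = 32)) / 2)
  const <- cine_movie(array(2, c(3, 8, 8)))
  expect_equal(roi_cov(const, roi), 0)
  scaled <- m; scaled$data <- 7 * m$data
  expect_equal(roi_cov(scaled, roi), roi_cov(m, roi))
  expect_equal(normalized_mean_signal(m, roi, m), 1)
  half <- m; half$data <- m$data / 2
  expect_equal(normalized_mean_signal(half, roi, m), 0.5)
  zero <- cine_movie(array(0, c(1, 8, 8)))
  expect_error(normalized_mean_signal(m, roi, zero), "reference ROI mean")
})

test_that("Dice overlap handles the standard and degenerate cases", {
  a <- roi_mask(matrix(c(rep(TRUE, 100), rep(FALSE, 156)), 16, 16))
  expect_equal(dice_coefficient(a, a), 1)
  b <- roi_mask(matrix(c(rep(FALSE, 156), rep(TRUE, 100)), 16, 16))
  expect_equal(dice_coefficient(a, b), 0)
  # |A| = |B| = 100 with overlap 50
  c1 <- roi_mask(matrix(c(rep(TRUE, 100), rep(FALSE, 156)), 16, 16))
  c2 <- roi_mask(matrix(c(rep(FALSE, 50), rep(TRUE, 100), rep(FALSE, 106)),
                        16, 16))
  expect_equal(dice_coefficient(c1, c2), 0.5)
  e <- roi_mask(matrix(FALSE, 16, 16))
  expect_equal(dice_coefficient(e, e), 1)
  expect_equal(dice_coefficient(e, a), 0)
  expect_error(dice_coefficient(a, roi_mask(matrix(TRUE, 8, 8))), "geometry")
})

test_that("evaluate_set tabulates every source, metric and ROI deterministically", {
  set <- tiny_lv_set()
  tab <- evaluate_set(set, methods = list(identity_ref = set$reference),
                      rois = "heart")
  id_rows <- tab[tab$source == "identity_ref", ]
  expect_identical(id_rows$value[id_rows$metric == "psnr"], Inf)
  expect_equal(id_rows$value[id_rows$metric == "ssim"], 1)
  # 2 inputs + 1 method, 4 metrics each on one ROI
  expect_equal(nrow(tab), 3 * 4)
  expect_identical(tab, evaluate_set(set,
                                     methods = list(identity_ref = set$reference),
                                     rois = "heart"))
  noref <- set; noref$reference <- NULL
  expect_error(evaluate_set(noref, list()), "reference")
})
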