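small_net <- function(levels = 2, ch = 3, seed = 3)
  build_network(net_config(n_levels = levels, base_channels = ch), seed = seed)

randomize_head <- function(model, seed = 4) {
  set.seed(seed)
  model$params$head$W[] <- rnorm(length(model$params$head$W), sd = 0.1)
  model$params$head$b[] <- rnorm(length(model$params$head$b), sd = 0.1)
  model
}

test_that("untrained network reproduces the two-point average exactly", {
  m <- small_net()
  a1 <- rand_movie(c(4, 16, 16), 1)$data
  a2 <- rand_movie(c(4, 16, 16), 2)$data
  out <- symmetrized_inference(m, a1, a2)
  expect_equal(out, (a1 + a2) / 2, tolerance = 1e-12)
})

test_that("output geometry equals input geometry, including odd sizes", {
  m <- small_net()
  for (d in list(c(4, 16, 16), c(5, 21, 19))) {
    out <- symmetrized_inference(m, array(1, d), array(2, d))
    expect_identical(dim(out), as.integer(d))
  }
})

test_that("symmetrized inference is order-invariant for any weights", {
  m <- randomize_head(small_net())
  p1 <- rand_movie(c(4, 16, 16), 5)
  p2 <- rand_movie(c(4, 16, 16), 6)
  o12 <- symmetrized_inference(m, p1, p2)
  o21 <- symmetrized_inference(m, p2, p1)
  expect_lt(max(abs(o12$data - o21$data)) / max(o12$data), 1e-5)
  expect_identical(o12$data, symmetrized_inference(m, p1, p2)$data)
  # identical inputs: symmetrization coincides with one forward pass
  nz <- normalize_pair(p1$data, p1$data)
  single <- pccine:::net_apply_sym(m, nz$p1, nz$p2) * nz$scale
  expect_equal(symmetrized_inference(m, p1, p1)$data, pmax(single, 0))
})

test_that("weight sharing is structural, not a copy", {
  m <- small_net()
  # one parameter set serves both encoder branches: all layer names unique,
  # none branch-specific, and the count matches the layer table
  expect_false(any(duplicated(names(m$params))))
  expect_identical(names(m$params), names(pccine:::net_layers(m$config)))
  analytic <- sum(vapply(pccine:::net_layers(m$config), function(l)
    l$k * l$cin * l$cout + l$cout, numeric(1)))
  expect_equal(n_parameters(m), analytic)
})

test_that("shared normalization preserves the inter-movie intensity ratio", {
  a <- array(10, c(2, 8, 8)); b <- array(10, c(2, 8, 8))
  nz <- normalize_pair(a, b)
  expect_equal(nz$scale, 10)
  expect_equal(max(abs(nz$p1 - 1)), 0)
  a2 <- rand_movie(c(2, 8, 8), 7)$data; b2 <- 0.3 * a2
  nz1 <- normalize_pair(a2, b2)
  nz2 <- normalize_pair(5 * a2, 5 * b2)
  expect_equal(nz2$scale, 5 * nz1$scale)
  expect_equal(nz2$p1, nz1$p1)
  expect_equal(nz1$p2 / nz1$p1, b2 / a2)
  z <- array(0, c(2, 8, 8))
  expect_warning(nz0 <- normalize_pair(z, z), "all-zero")
  expect_equal(nz0$scale, 1)
})

test_that("backpropagated gradients match finite differences", {
  m <- randomize_head(small_net(ch = 2))
  s <- list(p1 = rand_movie(c(3, 8, 8), 8)$data,
            p2 = rand_movie(c(3, 8, 8), 9)$data)
  s$label <- (s$p1 + s$p2) / 2 + 0.1 * rand_movie(c(3, 8, 8), 10)$data
  grads <- new.env(parent = emptyenv())
  loss0 <- pccine:::sym_loss_and_grads(m, s, grads)
  g <- as.list(grads)
  eps <- 1e-6
  set.seed(11)
  for (nm in c("enc1a", "enc2b", "dec1a", "head")) {
    for (rep in 1:2) {
      i <- sample(length(m$params[[nm]]$W), 1)
      mp <- m
      mp$params[[nm]]$W[i] <- mp$params[[nm]]$W[i] + eps
      g2 <- new.env(parent = emptyenv())
      lp <- pccine:::sym_loss_and_grads(mp, s, g2)
      expect_equal((lp - loss0) / eps, g[[nm]]$W[i], tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  scenes <- lapply(1:3, function(i) {
    sc <- sample_scene("lv_short_axis", seed = 100 + i, grid = c(32, 32),
                       n_frames = 4)
    render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
  })
  samples <- make_training_samples(scenes)
  cfg <- train_config(steps = 150, lr = 2e-3, crop = c(4, 16, 16),
                      val_every = 75, seed = 21)
  untrained <- build_network(net_config(2, 4), seed = 21)
  vl0 <- pccine:::validation_loss(untrained, samples)
  m1 <- train_network(build_network(net_config(2, 4), seed = 21), samples,
                      cfg, val_samples = samples)
  expect_lt(tail(m1$history$validation$loss, 1), vl0)
  m2 <- train_network(build_network(net_config(2, 4), seed = 21), samples,
                      cfg, val_samples = samples)
  expect_identical(m1$history$train$loss, m2$history$train$loss)
  expect_error(train_network(build_network(net_config(2, 4)), list(), cfg),
               "empty")
})

test_that("the residual base solves the averaging toy task", {
  # label equals (p1+p2)/2: the zero-initialized head is already optimal,
  # and brief training keeps the validation loss at the noise floor
  samples <- lapply(1:2, function(i)
    list(p1 = rand_movie(c(4, 16, 16), 30 + i)$data,
         p2 = rand_movie(c(4, 16, 16), 40 + i)$data))
  samples <- lapply(samples, function(s) {
    s$label <- (s$p1 + s$p2) / 2
    s
  })
  cfg <- train_config(steps = 30, lr = 1e-4, crop = c(4, 16, 16), seed = 3,
                      val_every = 30)
  m <- train_network(build_network(net_config(2, 3), seed = 3), samples, cfg,
                     val_samples = samples)
  expect_lt(tail(m$history$validation$loss, 1), 1e-3)
})
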