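test_that("B0 maps combine polynomial background and focal gradient", {
  cfg0 <- phantom_config(grid = c(32, 32), n_frames = 4)
  expect_equal(make_b0_map(cfg0), matrix(0, 32, 32))
  # focal center aligned with a pixel: map there is background + amplitude
  cfg <- phantom_config(grid = c(32, 32), n_frames = 4,
                        b0 = list(poly = c(25, 0, 0, 0, 0, 0),
                                  focal_amp_hz = 140,
                                  focal_center = c(0.5, 0.5),
                                  focal_width = 0.15))
  map <- make_b0_map(cfg)
  expect_equal(map[16, 16], 25 + 140)
  expect_identical(map, make_b0_map(cfg))
})

test_that("zero off-resonance at psi = 180 renders the reference exactly", {
  sc <- static_lv_scene(poly = rep(0, 6), focal = 0)
  set <- render_phase_cycled_cine(sc$config, sc$protocol, 180)
  expect_lt(max(abs(set$movies[[1]]$data - set$reference$data)) /
              max(set$reference$data), 1e-6)
})

test_that("rendering is reproducible from the seed", {
  sc <- make_default_scene("lv_short_axis", grid = c(32, 32), n_frames = 6,
                           seed = 11)
  a <- render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
  b <- render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
  expect_identical(a$movies[[1]]$data, b$movies[[1]]$data)
  expect_identical(a$movies[[2]]$data, b$movies[[2]]$data)
  sc$config$seed <- 12L
  c2 <- render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
  expect_false(identical(a$movies[[1]]$data, c2$movies[[1]]$data))
  expect_error(render_phase_cycled_cine(sc$config, sc$protocol, c(90, 90)),
               "duplicate")
})

test_that("the reference movie is invariant to the rendered psi set", {
  sc <- make_default_scene("lv_short_axis", grid = c(32, 32), n_frames = 6)
  a <- render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
  b <- render_phase_cycled_cine(sc$config, sc$protocol, c(180, 360))
  expect_identical(a$reference$data, b$reference$data)
  expect_true(all(a$movies[[1]]$data >= 0))
  expect_true(all(vapply(a$masks, function(m)
    identical(dim(m$data), c(32L, 32L)), logical(1))))
})

test_that("opposite increments put their dark bands half a FOV apart on a linear field", {
  # linear B0 spanning [-1/(2TR), +1/(2TR)] left to right
  p <- testing_protocol()
  span <- 1000 / (2 * p$tr_ms)
  cfg <- phantom_config(
    grid = c(32, 64), n_frames = 4,
    regions = list(list(center = c(0.5, 0.5), axes = c(3, 3),
                        tissue = tissue_params(1900, 250), contract = 0)),
    b0 = list(poly = c(0, 0, span, 0, 0, 0), focal_amp_hz = 0,
              focal_center = c(0.5, 0.5), focal_width = 0.1),
    noise_sigma = 0)
  set <- render_phase_cycled_cine(cfg, p, c(90, 270))
  band_col <- vapply(set$movies, function(m)
    which.min(colMeans(m$data[1, , ])), numeric(1))
  expect_equal(abs(band_col[["90"]] - band_col[["270"]]), 32, tolerance = 2)
})

test_that("shifting the B0 map reproduces a different increment (simulator equivalence)", {
  p <- testing_protocol()
  sc <- static_lv_scene()
  a <- render_phase_cycled_cine(sc$config, p, 90)
  sc2 <- sc
  sc2$config$b0$poly[1] <- sc$config$b0$poly[1] + (150 - 90) / 360 *
    1000 / p$tr_ms
  b <- render_phase_cycled_cine(sc2$config, p, 150)
  expect_equal(a$movies[[1]]$data, b$movies[[1]]$data, tolerance = 1e-10)
})

test_that("presets provide the documented anatomy and artifact severity", {
  sc <- make_default_scene("lv_short_axis")
  expect_gte(length(sc$config$regions), 3)
  expect_gte(length(sc$config$flow_regions), 1)
  t0 <- Sys.time()
  set <- render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
  la <- make_default_scene("la_view")
  set_la <- render_phase_cycled_cine(la$config, la$protocol, 180)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
  expect_identical(dim(set$movies[[1]]$data), c(12L, 128L, 128L))
  # large-area void: blood-pool signal collapses at psi = 180 in the LA view
  nms <- normalized_mean_signal(set_la$movies[[1]], set_la$masks$la_cavity,
                                set_la$reference)
  expect_lt(nms, 0.6)
  expect_error(make_default_scene("no_such_preset"))
})

test_that("sampled scenes vary but stay renderable", {
  s1 <- sample_scene("lv_short_axis", seed = 5, grid = c(32, 32), n_frames = 4)
  s2 <- sample_scene("lv_short_axis", seed = 6, grid = c(32, 32), n_frames = 4)
  expect_false(identical(s1$config$b0, s2$config$b0))
  set <- render_phase_cycled_cine(s1$config, s1$protocol, c(90, 270))
  expect_true(all(is.finite(set$movies[[1]]$data)))
  expect_gte(sum(set$masks$heart$data), 8)
})
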