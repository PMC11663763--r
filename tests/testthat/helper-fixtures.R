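# shared fixtures, all generated in code; heavier objects are memoized so
# the suite builds them once

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

testing_protocol <- function() scan_protocol(tr_ms = 2.98, te_ms = 1.37,
                                             flip_deg = 60,
                                             views_per_segment = 24)

# small rendered LV scene shared across tests
tiny_lv_set <- function() memo("tiny_lv", function() {
  sc <- make_default_scene("lv_short_axis", grid = c(32, 32), n_frames = 6)
  render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
})

# noise-free, flow-free variant of the LV scene for exact comparisons
static_lv_scene <- function(poly = c(20, 10, 30, 0, 0, 0), focal = 140) {
  sc <- make_default_scene("lv_short_axis", grid = c(32, 32), n_frames = 6)
  sc$config$noise_sigma <- 0
  sc$config$flow_regions <- list()
  sc$config$b0$poly <- poly
  sc$config$b0$focal_amp_hz <- focal
  sc
}

# integer-pixel shift of a (t, y, x) array with zero fill
shift_arr <- function(arr, dy, dx) {
  d <- dim(arr)
  out <- array(0, d)
  ys <- seq_len(d[2]) - dy; xs <- seq_len(d[3]) - dx
  oky <- ys >= 1 & ys <= d[2]; okx <- xs >= 1 & xs <= d[3]
  out[, oky, okx] <- arr[, ys[oky], xs[okx]]
  out
}

rand_movie <- function(dims, seed) {
  set.seed(seed)
  cine_movie(array(abs(rnorm(prod(dims))), dims))
}

# --- acceptance-scale experiment, shared by the recovery and LA criteria ---
# 20 training + 6 held-out LV scenes at 48x48x8, dual-encoder network with
# 3 levels / 6 base channels trained 3200 steps on clean-reference labels
acceptance_scenes <- function() memo("acc_scenes", function() {
  lapply(seq_len(26), function(i) {
    sc <- sample_scene("lv_short_axis", seed = 1000 + i, grid = c(48, 48),
                       n_frames = 8)
    render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
  })
})

acceptance_model <- function() memo("acc_model", function() {
  scenes <- acceptance_scenes()
  samples <- make_training_samples(scenes[1:20])
  cfg <- train_config(steps = 3200, lr = 1e-3, crop = c(6, 24, 24),
                      lr_decay_at = c(1800, 2500, 3000), val_every = 1600,
                      seed = 7)
  model <- build_network(net_config(n_levels = 3, base_channels = 6),
                         seed = 7)
  train_network(model, samples, cfg)
})
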