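test_that("steady-state signal has the expected degenerate limits", {
  p <- testing_protocol()
  # zero flip angle or zero density give zero signal
  expect_equal(Mod(pccine:::ss_signal_vec(1000, 200, 1, 50, p$tr_ms, p$te_ms,
                                          0, 180)), 0)
  expect_equal(ssfp_steady_state(tissue_params(1000, 200, rho = 0), p, 180),
               0 + 0i)
  # linear in proton density
  m1 <- ssfp_steady_state(tissue_params(1000, 200, rho = 1, df_hz = 37), p, 90)
  m2 <- ssfp_steady_state(tissue_params(1000, 200, rho = 2, df_hz = 37), p, 90)
  expect_equal(m2, 2 * m1)
  # periodic in off-resonance with period 1/TR
  per <- 1000 / p$tr_ms
  for (k in c(1, -2)) {
    a <- Mod(ssfp_steady_state(tissue_params(1200, 60, df_hz = 21), p, 270))
    b <- Mod(ssfp_steady_state(tissue_params(1200, 60, df_hz = 21 + k * per),
                               p, 270))
    expect_equal(a, b, tolerance = 1e-12)
  }
  expect_error(tissue_params(100, 200), "t1_ms >= t2_ms")
})

test_that("Bloch transient converges to the closed-form steady state", {
  p <- testing_protocol()
  ts <- tissue_params(1000, 200, df_hz = 0)
  e <- bloch_transient(ts, p, 180, n_tr = 3000)
  m <- ssfp_steady_state(ts, p, 180)
  expect_lt(Mod(e[3000] - m) / Mod(m), 1e-5)
  expect_error(bloch_transient(ts, p, 180, n_tr = 0), "n_tr")
})

test_that("transient/closed-form agreement holds over a parameter grid", {
  p0 <- testing_protocol()
  for (t1 in c(400, 1200, 1900)) for (t2_frac in c(0.05, 0.5)) {
    t2 <- t1 * t2_frac
    for (flip in c(35, 60)) for (df in c(-120, 15, 80)) {
      psi <- (df * 7) %% 360 + 10   # varied but deterministic
      p <- scan_protocol(tr_ms = p0$tr_ms, te_ms = p0$te_ms, flip_deg = flip,
                         phase_increments_deg = c(90, 270))
      ts <- tissue_params(t1, t2, df_hz = df)
      # the transient decays at a flip-angle-weighted mix of 1/T1 and 1/T2,
      # slowest near T1 for small flips; 15 T1 is a safe horizon for 1e-5
      n <- ceiling(15 * t1 / p$tr_ms)
      e <- bloch_transient(ts, p, psi, n_tr = n)
      m <- ssfp_steady_state(ts, p, psi)
      expect_lt(Mod(e[n] - m) / Mod(m), 1e-5)
    }
  }
})

test_that("first transient echo reflects single-pulse geometry", {
  # TE -> 0: first echo magnitude is rho * sin(alpha), independent of df
  p <- scan_protocol(tr_ms = 2.98, te_ms = 1e-4, flip_deg = 60)
  ts <- tissue_params(1000, 200, rho = 1.3, df_hz = 95)
  e <- bloch_transient(ts, p, 180, n_tr = 2)
  expect_equal(Mod(e[1]), 1.3 * sin(60 * pi / 180), tolerance = 1e-5)
  # zero flip angle: all echoes vanish
  e0 <- pccine:::bloch_transient_vec(1000, 200, 1, 50, 2.98, 1.37, 0, 180, 10)
  expect_equal(max(Mod(e0)), 0)
})

test_that("inflow reduces to the stationary signal and hyperenhances at the band", {
  p <- testing_protocol()
  null_df <- band_null_offset(p, 180)
  blood <- tissue_params(1900, 250, df_hz = null_df)
  still <- flow_spec(rep(0, 5), tissue = blood)
  expect_equal(inflow_signal(still, p, 180),
               rep(Mod(ssfp_steady_state(blood, p, 180)), 5))
  # fast flow at the banding null: fresh spins are much brighter than the
  # steady state (the hyperintense flow artifact)
  fast <- flow_spec(c(2700, 2700), tissue = blood)
  sig <- inflow_signal(fast, p, 180)
  expect_true(all(sig > 10 * Mod(ssfp_steady_state(blood, p, 180))))
  expect_equal(sig[1], 1 * sin(p$flip_deg * pi / 180) *
                 exp(-p$te_ms / 250), tolerance = 0.05)
  # linear in proton density
  blood2 <- tissue_params(1900, 250, rho = 2, df_hz = null_df)
  fast2 <- flow_spec(c(2700, 2700), tissue = blood2)
  expect_equal(inflow_signal(fast2, p, 180), 2 * sig)
  expect_true(all(inflow_signal(flow_spec(c(0, 33, 400), tissue = blood),
                                p, 90) >= 0))
})

test_that("band nulls sit at psi/(360 TR) and minimize the profile", {
  p <- testing_protocol()
  expect_equal(band_null_offset(p, 0), 0)
  expect_equal(band_null_offset(p, 180), 1000 / (2 * p$tr_ms))
  # numerical minimum of the magnitude profile agrees with the closed form
  ts <- tissue_params(1000, 200)
  for (psi in c(90, 180, 300)) {
    pred <- band_null_offset(p, psi)
    opt <- optimize(function(df)
      Mod(ssfp_steady_state(tissue_params(1000, 200, df_hz = df), p, psi)),
      interval = pred + c(-60, 60))
    expect_equal(opt$minimum, pred, tolerance = 0.5)
  }
  # opposite increments are offset by exactly half the banding period
  d <- (band_null_offset(p, 250 + 180) - band_null_offset(p, 250)) %%
    (1000 / p$tr_ms)
  expect_equal(d, 1000 / (2 * p$tr_ms))
})

test_that("shifting the RF increment rigidly translates the banding profile", {
  p <- testing_protocol()
  tr_s <- p$tr_ms / 1000
  set.seed(42)
  for (i in 1:20) {
    delta <- runif(1, -2 * pi, 2 * pi)       # radians
    df <- runif(1, -300, 300); psi <- runif(1, 0, 360)
    a <- Mod(ssfp_steady_state(tissue_params(1100, 90, df_hz = df), p, psi))
    b <- Mod(ssfp_steady_state(
      tissue_params(1100, 90, df_hz = df + delta / (2 * pi * tr_s)), p,
      psi + delta * 180 / pi))
    expect_equal(a, b, tolerance = 1e-10)
  }
})
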