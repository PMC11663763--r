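# pccine

Phase-cycled bSSFP cine simulation and dual-encoder artifact suppression.

## What this is for

Balanced steady-state free precession (bSSFP) cine is the standard sequence
for cardiac function imaging, but its magnitude response is periodic in the
per-TR off-resonance precession: wherever `2*pi*df*TR` matches the RF phase
increment `psi` (mod 2*pi), the signal collapses into a dark **banding**
artifact, and spins flowing through off-resonant regions produce
hyperintense, pulsatile **flow** artifacts.  Acquiring *two* movies with
half-cycle-apart increments (`psi`, `psi + 180°`) in a single 12-heartbeat
breath-hold shifts the banding pattern by exactly `1/(2*TR)` Hz between
them, so every location is artifact-free in at least one movie — the
question is how to combine the pair.

`pccine` is a desk-scale laboratory for this problem, aimed at MRI methods
researchers.  It provides:

* a physics-based simulator of phase-cycled 2D+time cine sets — closed-form
  bSSFP steady state, a brute-force Bloch transient iterator (the oracle for
  the closed form and the engine of the inflow/flow-artifact model),
  polynomial + focal B0 fields, beating ellipse phantoms, Rician noise, and
  matched artifact-free references;
* the classical combinations: the two-point magnitude average and the
  short-range phase-cycling (SPC) label — the mean of the movies at
  `psi = 120°...240°` after rigid registration to the 180° movie;
* a dual-encoder, weight-sharing 2D+time convolutional network with
  residual design (output = two-point average + learned correction) and
  order-invariant symmetrized inference,
  `output(p1, p2) = (network(p1, p2) + network(p2, p1)) / 2`,
  plus a seeded CPU training harness;
* ROI image-quality metrics: PSNR, Gaussian-window SSIM, coefficient of
  variation, normalized mean signal, and Dice overlap;
* NIfTI + JSON-sidecar I/O and a command-line interface
  (`inst/cli/pccine`) covering `simulate`, `combine`, `train`, `infer`,
  `eval` and `profile-plot`.

## Worked example

```r
library(pccine)

scene <- make_default_scene("lv_short_axis", grid = c(64, 64), n_frames = 8)
set <- render_phase_cycled_cine(scene$config, scene$protocol, psis = c(90, 270))
set
#> phase_cycled_set: 2 movie(s) (psi = 90/270), 8 x 64 x 64, with reference, masks: heart, flow

avg <- average_combine(set$movies)
tab <- evaluate_set(set, methods = list(average = avg), rois = "heart")
tab[tab$metric %in% c("psnr", "ssim"), ]
#>   source metric   roi  value
#>   psi_90   psnr heart  8.317
#>   psi_90   ssim heart  0.418
#>  psi_270   psnr heart 26.492
#>  psi_270   ssim heart  0.905
#>  average   psnr heart 13.955
#>  average   ssim heart  0.806
```

The default scene puts a ~140 Hz focal off-resonance over the heart: the
90° movie has a deep band crossing the heart ROI (8.3 dB against the clean
reference), the 270° movie is mostly clean (26.5 dB), and the plain
two-point average inherits a half-depth band (14.0 dB) — which is exactly
why a nonlinear combination is needed.  Training the dual-encoder network
on sampled scenes and applying `symmetrized_inference()` lifts the
held-out heart-ROI PSNR above the *better* of the two inputs (about
29 dB mean versus 27 dB under the default experiment; run the acceptance
script below to reproduce).  The banding nulls of the two movies are
`band_null_offset(scene$protocol, 270) - band_null_offset(scene$protocol, 90)`
= 167.8 Hz apart, i.e. exactly `1/(2*TR)`.

A trained model is produced programmatically:

```r
scenes <- lapply(1:20, function(i) {
  sc <- sample_scene("lv_short_axis", seed = i, grid = c(48, 48), n_frames = 8)
  render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
})
model <- build_network(net_config(n_levels = 3, base_channels = 6), seed = 1)
model <- train_network(model, make_training_samples(scenes),
                       train_config(steps = 3200, lr = 1e-3,
                                    crop = c(6, 24, 24),
                                    lr_decay_at = c(1800, 2500, 3000),
                                    seed = 1))
out <- symmetrized_inference(model, set$movies[[1]], set$movies[[2]])
```

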