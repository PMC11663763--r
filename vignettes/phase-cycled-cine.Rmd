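---
title: "Simulating and suppressing bSSFP cine banding and flow artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and suppressing bSSFP cine banding and flow artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Balanced steady-state free precession (bSSFP) is the workhorse sequence of
cardiac cine imaging because of its high signal-to-noise ratio and
blood-myocardium contrast.  Its weakness is off-resonance sensitivity: the
steady-state magnitude is periodic in the per-repetition precession angle
and collapses to a null once per cycle.  Wherever the local B0 offset
$\Delta f$ satisfies $2\pi \Delta f \, TR \equiv \psi \pmod{2\pi}$, with
$\psi$ the per-TR radiofrequency (RF) phase increment, the image shows a
dark *banding* artifact.  Spins flowing through off-resonant regions never
reach the steady state; their transient echoes can far exceed the
steady-state level, producing hyperintense, time-varying *flow* artifacts.

Acquiring two cine movies with half-cycle-apart increments ($\psi$ and
$\psi + 180°$) in one 12-heartbeat breath-hold shifts the banding pattern
by half its period between the two movies, so every location is clean in
at least one of them.  The package implements this twofold phase-cycled
acquisition model end to end at desk scale: a physics-based simulator of
phase-cycled cine sets, the classical magnitude combinations, a
dual-encoder 2D+time convolutional network that fuses the pair, and the
ROI image-quality metrics used to evaluate the result.

## Signal model

`ssfp_steady_state()` evaluates the closed-form steady-state transverse
magnetization at the echo time,

$$
M = \rho\,(1 - E_1)\sin\alpha\;
\frac{1 - E_2 e^{-i\theta}}
     {(1 - E_1\cos\alpha)(1 - E_2\cos\theta) - E_2(E_1 - \cos\alpha)(E_2 - \cos\theta)}
\; e^{i\varphi\,TE/TR}\, e^{-TE/T_2},
$$

with $E_{1,2} = e^{-TR/T_{1,2}}$, $\varphi = 2\pi\Delta f\,TR$ and
$\theta = \varphi - \psi$.  The sign convention ($\theta = \varphi - \psi$,
positive $\Delta f$ precessing counterclockwise) makes $\psi = 180°$ place
on-resonant spins mid-passband, the standard choice.  The magnitude null
sits at $\theta \equiv 0$, i.e. at $\Delta f = \psi/(360°\,TR)$ modulo
$1/TR$ (`band_null_offset()`), so nulls of $\psi$ and $\psi + 180°$ are
exactly $1/(2TR)$ apart — the entire method rests on this rigid
translation property, which the test suite checks to $10^{-10}$.

`bloch_transient()` is the package's independent oracle for this formula:
it iterates the per-TR recursion directly — an $\alpha$ rotation about an
axis whose azimuth advances by $\psi$ each TR, free precession, and
$T_1/T_2$ relaxation — and its echo sequence converges to the closed form.
One practical detail: the transient decays at the flip-angle-weighted rate
$\cos^2(\alpha/2)/T_1 + \sin^2(\alpha/2)/T_2$, which for moderate flip
angles is close to $1/T_1$; reaching agreement at the $10^{-5}$ level
therefore needs a horizon of roughly $15\,T_1/TR$ repetitions, which is
what the tests simulate.

The same transient engine drives the flow model.  `inflow_signal()` treats
a vessel voxel as plug flow: at frame $f$ with through-plane velocity
$v(f)$, spins dwell for $n \approx \mathrm{thickness}/(v\,TR)$ repetitions,
so the voxel holds cohorts that entered $1,\dots,n$ TRs ago and its
magnitude is the mean of the first $n$ transient echo magnitudes.  Near a
banding null the early echoes are far brighter than the steady state,
reproducing the hyperintense, pulsatile flow artifact; at $v = 0$ the
model reduces exactly to the stationary steady state.

## The synthetic-data generator

`make_default_scene()` builds ellipse-based 2D+time scenes; all geometry
is in grid fractions so scenes rescale cleanly.

* `lv_short_axis`: torso, fatty wedge, left-ventricular myocardium and
  cavity, right-ventricular cavity, and a pulsatile descending aorta as a
  flow region.  Cardiac motion is a sinusoidal per-frame scaling of the
  ellipse axes (peak cavity contraction 28%), not elastic deformation —
  enough to give the 2D+time network temporal structure at desk scale.
* `la_view`: a left-atrial blood pool with atrial wall and a
  pulmonary-vein ostium carrying inflow.  A wide Gaussian focal
  off-resonance of $1.1/(2TR) \approx 185$ Hz is centred on the blood
  pool, so a single movie at $\psi = 180°$ shows a large-area signal void
  covering much of the cavity ROI, the scenario in which single-movie
  methods fail.

Tissue parameters are standard 3 T values (blood 1900/250 ms, myocardium
1470/47 ms, muscle 1400/40 ms, fat 380/130 ms).  The B0 field is a
second-order polynomial background plus a Gaussian focal gradient; the
scan protocol defaults to the twofold cine timing (TR/TE 2.98/1.37 ms,
flip 60°, 24 views per segment, increments 90°/270°).  Noise is Rician:
complex Gaussian noise of standard deviation `noise_sigma` (relative to
the peak reference signal, default 0.02) is added in quadrature before
taking magnitudes.  Each set carries a matched artifact-free reference —
every voxel rendered at its mid-passband signal, flow regions stationary,
noise-free — which serves as ground truth for training and metrics.

`sample_scene()` jitters geometry, field (focal amplitude uniformly in
±(90–190) Hz over the heart, polynomial terms up to ±40 Hz), noise
(0.015–0.03) and flow velocity to produce datasets of distinct but
comparable scenes.  The focal gradient is kept over the heart so banding
crosses the heart ROI in one of the two movies of most scenes — the study
condition under which combining the pair is actually needed.

What the generator does *not* emulate: realistic anatomy, elastic
deformation, respiratory drift, coil sensitivities, k-space sampling and
its artifacts.  Passing tests on these scenes demonstrate that the
algorithms behave as designed under controlled physics, not clinical
performance.

## Classical combinations

`average_combine()` is the two-point average baseline: the voxel-wise
mean of the magnitude movies (magnitude domain throughout, matching
processing of DICOM-derived data).  Averaging flattens the overall
magnitude response but only halves the band depth and averages flow
artifacts into both movies.  `spc_label()` implements the short-range
phase-cycling label: the mean of the five movies at
$\psi \in \{120°, 150°, 180°, 210°, 240°\}$, each first rigidly registered
to the 180° movie.  Registration (`rigid_register()`) estimates one
transform per movie — breath-hold misregistration is constant within a
movie — by maximizing normalized cross-correlation of the temporal-mean
images over integer shifts with parabolic subpixel refinement, optional
small-rotation search, and bilinear resampling; structureless or constant
images return the identity with a warning rather than a spurious shift.

## The dual-encoder network

`build_network()` constructs a U-Net-style 2D+time convolutional network
with two encoder branches that *share one parameter set* (sharing is
structural: both branches reference the same arrays, so the parameter
count is independent of input order).  All kernels are 3×3 spatial × 3
temporal; downsampling halves only the spatial axes.  At every level the
two branches' feature maps are fused by channel concatenation and fed to
a single decoder.  The network is residual: its output is the two-point
average $(p_1 + p_2)/2$ plus a learned correction whose final 1×1×1 layer
is zero-initialized.  An untrained network therefore reproduces the
averaging baseline exactly, which both stabilizes short training runs and
makes "improvement over the baseline" the only meaningful reading of the
trained result.  Order invariance is enforced at inference
(`symmetrized_inference()`): the prediction is computed for both input
orders and averaged, so it holds for *any* weights, trained or not.

Defaults are deliberately desk-scale: 3 levels with 6–8 base channels
(roughly 0.1–0.2 M parameters), no normalization layers (small-batch
training with Adam was stable without them, and they would enlarge the
hand-written backpropagation surface), rectified-linear activations, mean
absolute error on jointly normalized magnitudes (both movies divided by
the shared 99th percentile, preserving the inter-movie intensity
relationship that encodes banding), Adam with step-decayed learning rate,
random spatiotemporal crops with flip/swap augmentation.  All of these
are configurable (`net_config()`, `train_config()`) and recorded in
checkpoints.

## Evaluation metrics

`roi_psnr()` uses peak $L$ = reference maximum within the ROI (a bounded,
reference-anchored convention that makes PSNR jointly scale-invariant
with the RMSE).  `roi_ssim()` is the standard Gaussian-window SSIM
(11×11, $\sigma$ 1.5, $K_1 = 0.01$, $K_2 = 0.03$, dynamic range = ROI
maximum of the reference), computed per frame and averaged over ROI
pixels; the implementation agrees with scikit-image's
`structural_similarity` to $10^{-6}$ on interior ROIs (frozen
cross-check in the test suite).  `roi_cov()` is the per-frame
std/mean averaged across frames (the pooled-voxel alternative differs
only in weighting); `normalized_mean_signal()` divides the ROI mean by
the reference ROI mean, frames pooled.  `dice_coefficient()` defines
empty-vs-empty as 1 and empty-vs-nonempty as 0, the convention continuous
at the boundary.  Metrics refuse ROIs under 8 pixels.

## Numerical choices and degenerate inputs

* Convolution boundaries are zero-padded ("same"); the divisibility
  requirement of the multi-level network is met by reflective padding
  that is cropped back after inference, so output geometry always equals
  input geometry.
* Identical movies give PSNR `Inf` (reported as such) rather than an
  error; all-zero pairs normalize with factor 1 and a warning.
* Registration searches ±8 px by default and treats a peak correlation
  under 0.2 as "no reliable structure", returning the identity with a
  warning.
* The banding-null finder is closed-form; the tests verify it against
  numerical minimization of the profile.
* All randomness (phantom noise, scene sampling, weight initialization,
  crop/augmentation sampling) is seeded; two runs with the same seed are
  bit-identical.

## Problem sizes used by the tests and the acceptance script

The recovery experiment trains on 20 sampled left-ventricular scenes of
48×48 pixels × 8 frames (inputs $\psi$ = 90°/270°, clean-reference
labels), with a 3-level/6-channel network, 3 200 Adam steps at learning
rate $10^{-3}$ (decayed ×0.3 at steps 1 800, 2 500 and 3 000) on
24×24×6 crops, then evaluates heart-ROI PSNR on 6 held-out scenes
against the better single input and the two-point average.  The same
trained model is applied unchanged to the `la_view` scene to probe
large-area banding suppression.  These sizes were chosen so the full
experiment trains in minutes on a single CPU while leaving the
qualitative orderings of the full-scale method intact; scaling the grid,
scene count or step budget up is a configuration change, not a code
change.

## Known limitations

* The phantom's motion model is affine scaling of ellipses; it cannot
  probe motion-induced misregistration between the two movies of a
  breath-hold beyond the rigid offsets the registration module handles.
* The flow model is plug flow with instantaneous replacement; partial
  volume ramps and in-plane flow are not modeled.
* The network is intentionally small; its absolute image quality is not
  comparable to a full-scale trained model, and conclusions from the
  synthetic experiments are directional (orderings), not quantitative
  claims about in-vivo performance.
* A single-movie degenerate mode (`p2 := p1`) exists for comparison but
  is not tuned; it shares the residual design, so untrained it returns
  the input movie itself.
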