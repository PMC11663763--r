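Package: pccine
Title: Phase-Cycled bSSFP Cine Simulation and Dual-Encoder Artifact
    Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying banding and flow artifacts in balanced
    steady-state free precession (bSSFP) cardiac cine imaging at desk scale.
    Provides a physics-based simulator of phase-cycled 2D+time cine movies
    (closed-form bSSFP steady state, a Bloch transient iterator, through-plane
    inflow, polynomial plus focal B0 fields, Rician noise), classical
    magnitude combinations (N-point averaging, short-range phase-cycling
    labels with rigid registration), a dual-encoder shared-weight 2D+time
    convolutional network with order-invariant symmetrized inference and a
    CPU training harness, ROI-based image-quality metrics (PSNR, SSIM,
    coefficient of variation, normalized mean signal, Dice), and NIfTI/JSON
    input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
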