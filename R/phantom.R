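#' 2D+time magnitude cine movie
#'
#' @param data Non-negative numeric array with dimensions
#'   (frames, rows, cols).
#' @param psi_deg RF phase increment of the acquisition, degrees (or `NA`
#'   for combined/reference movies).
#' @param tr_ms,te_ms,flip_deg Sequence timing metadata.
#' @param frame_duration_ms Duration of one cardiac phase.
#' @param combined_from For combination outputs, the contributing psi list.
#' @param label Optional tag (e.g. `"reference"`, `"spc"`).
#' @return An object of class `cine_movie`.
#' @export
cine_movie <- function(data, psi_deg = NA_real_, tr_ms = NA_real_,
                       te_ms = NA_real_, flip_deg = NA_real_,
                       frame_duration_ms = NA_real_, combined_from = NULL,
                       label = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3)
    stop("cine_movie: data must be a (frames, rows, cols) array")
  if (any(data < 0)) stop("cine_movie: magnitude data must be non-negative")
  structure(list(data = data, psi_deg = psi_deg, tr_ms = tr_ms, te_ms = te_ms,
                 flip_deg = flip_deg, frame_duration_ms = frame_duration_ms,
                 combined_from = combined_from, label = label),
            class = "cine_movie")
}

#' @export
print.cine_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("cine_movie: %d frames x %d x %d, psi = %s deg%s\n",
              d[1], d[2], d[3], format(x$psi_deg),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' @export
dim.cine_movie <- function(x) dim(x$data)

#' Binary region-of-interest mask
#'
#' @param data Logical (or 0/1) matrix of dimensions (rows, cols).
#' @param label Name of the ROI (e.g. `"heart"`, `"la_cavity"`).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, label = "roi") {
  data <- as.matrix(data)
  mode(data) <- "logical"
  structure(list(data = data, label = label), class = "roi_mask")
}

#' Co-registered set of phase-cycled cine movies
#'
#' @param movies Named list of [cine_movie()]s with identical geometry and
#'   distinct `psi_deg`.
#' @param reference Optional artifact-free [cine_movie()].
#' @param masks Named list of [roi_mask()]s.
#' @param protocol The [scan_protocol()] used.
#' @return An object of class `phase_cycled_set`.
#' @export
phase_cycled_set <- function(movies, reference = NULL, masks = list(),
                             protocol = NULL) {
  dims <- lapply(movies, function(m) dim(m$data))
  if (length(unique(dims)) != 1)
    stop("phase_cycled_set: movies must share geometry")
  psis <- vapply(movies, function(m) m$psi_deg, numeric(1))
  if (anyDuplicated(psis)) stop("phase_cycled_set: duplicate psi_deg")
  names(movies) <- as.character(psis)
  structure(list(movies = movies, reference = reference, masks = masks,
                 protocol = protocol), class = "phase_cycled_set")
}

#' @export
print.phase_cycled_set <- function(x, ...) {
  d <- dim(x$movies[[1]]$data)
  cat(sprintf("phase_cycled_set: %d movie(s) (psi = %s), %d x %d x %d, %s reference, masks: %s\n",
              length(x$movies), paste(names(x$movies), collapse = "/"),
              d[1], d[2], d[3],
              if (is.null(x$reference)) "no" else "with",
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Phantom configuration for the cine simulator
#'
#' Describes a deformable ellipse-based 2D+time scene: tissue regions
#' painted in order (later regions overwrite earlier ones), a smooth
#' polynomial B0 background with an added Gaussian focal off-resonance
#' gradient, through-plane flow regions, and Rician noise.  All geometry
#' is expressed in fractions of the grid so scenes rescale cleanly.
#'
#' @param grid `c(rows, cols)`, each >= 16.
#' @param n_frames Number of cardiac phases (>= 4).
#' @param regions List of static-tissue regions; each is a list with
#'   `center` (fractions), `axes` (fractions), `angle_deg`, `tissue`
#'   ([tissue_params()]) and `contract` (peak fractional shrinkage of the
#'   axes over the cardiac cycle).
#' @param b0 List with `poly` (coefficients `c0, cy, cx, cyy, cxy, cxx` in
#'   Hz over normalized coordinates in \[-1, 1\]), `focal_amp_hz`,
#'   `focal_center` (fractions) and `focal_width` (fraction of the grid).
#' @param flow_regions List of flow regions; each a list with `center`,
#'   `axes`, `angle_deg` and `flow` ([flow_spec()]).
#' @param noise_sigma Complex-Gaussian noise standard deviation relative
#'   to the peak reference signal.
#' @param masks Named list of ellipse specs (`center`, `axes`,
#'   `angle_deg`) rendered into [roi_mask()]s.
#' @param seed RNG seed making the rendered noise reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(128, 128), n_frames = 12, regions = list(),
                           b0 = list(poly = rep(0, 6), focal_amp_hz = 0,
                                     focal_center = c(0.5, 0.5),
                                     focal_width = 0.15),
                           flow_regions = list(), noise_sigma = 0,
                           masks = list(), seed = 1) {
  if (any(grid < 16)) stop("phantom_config: grid dimensions must be >= 16")
  if (n_frames < 4) stop("phantom_config: n_frames must be >= 4")
  if (noise_sigma < 0) stop("phantom_config: noise_sigma must be >= 0")
  b0$poly <- rep_len(as.numeric(b0$poly), 6)
  structure(list(grid = as.integer(grid), n_frames = as.integer(n_frames),
                 regions = regions, b0 = b0, flow_regions = flow_regions,
                 noise_sigma = noise_sigma, masks = masks,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# logical ellipse mask; center/axes in fractions of the grid, axes scaled by s
ellipse_mask <- function(grid, center, axes, angle_deg = 0, scale = 1) {
  ny <- grid[1]; nx <- grid[2]
  cy <- center[1] * ny; cx <- center[2] * nx
  ry <- max(axes[1] * ny * scale, 1e-6); rx <- max(axes[2] * nx * scale, 1e-6)
  a <- angle_deg * pi / 180
  Y <- matrix(seq_len(ny), ny, nx) - cy
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  U <- cos(a) * Y + sin(a) * X
  V <- -sin(a) * Y + cos(a) * X
  (U / ry)^2 + (V / rx)^2 <= 1
}

# sinusoidal systole/diastole schedule: scale 1 at frame 1, minimum
# (1 - contract) mid-cycle
contraction_scale <- function(contract, frame, n_frames) {
  1 - contract * sin(pi * (frame - 1) / n_frames)^2
}

#' Off-resonance (B0) map of a phantom
#'
#' Second-order polynomial background plus a Gaussian-shaped focal
#' gradient; deterministic given the configuration.
#'
#' @param config A [phantom_config()].
#' @return Numeric (rows x cols) matrix in Hz.
#' @export
make_b0_map <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  ny <- config$grid[1]; nx <- config$grid[2]
  yn <- matrix(seq(-1, 1, length.out = ny), ny, nx)
  xn <- matrix(seq(-1, 1, length.out = nx), ny, nx, byrow = TRUE)
  p <- config$b0$poly
  map <- p[1] + p[2] * yn + p[3] * xn + p[4] * yn^2 + p[5] * xn * yn +
    p[6] * xn^2
  if (config$b0$focal_amp_hz != 0) {
    fc <- config$b0$focal_center
    sig <- config$b0$focal_width * min(ny, nx)
    Y <- matrix(seq_len(ny), ny, nx) - fc[1] * ny
    X <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - fc[2] * nx
    map <- map + config$b0$focal_amp_hz * exp(-(Y^2 + X^2) / (2 * sig^2))
  }
  map
}

# one noise-free frame: paint static regions with the closed-form
# steady-state magnitude (b0 = NULL renders the banding-free reference)
render_frame <- function(config, protocol, psi_deg, frame, b0_map) {
  ny <- config$grid[1]; nx <- config$grid[2]
  img <- matrix(0, ny, nx)
  for (rg in config$regions) {
    s <- contraction_scale(rg$contract %||% 0, frame, config$n_frames)
    m <- ellipse_mask(config$grid, rg$center, rg$axes, rg$angle_deg %||% 0, s)
    ts <- rg$tissue
    if (is.null(b0_map)) {
      img[m] <- Mod(ss_signal_vec(ts$t1_ms, ts$t2_ms, ts$rho, 0,
                                  protocol$tr_ms, protocol$te_ms,
                                  protocol$flip_deg, 180))
    } else {
      img[m] <- Mod(ss_signal_vec(ts$t1_ms, ts$t2_ms, ts$rho, b0_map[m],
                                  protocol$tr_ms, protocol$te_ms,
                                  protocol$flip_deg, psi_deg))
    }
  }
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a phase-cycled cine set from a phantom
#'
#' For each requested RF phase increment, renders the noise-free movie
#' from the closed-form steady-state magnitude (static tissue) and the
#' transient inflow model (flow regions), adds complex Gaussian noise in
#' quadrature (Rician magnitude noise), and also renders a matched
#' artifact-free reference: every voxel at the mid-passband (on-resonant)
#' signal, flow regions at their stationary on-resonance signal,
#' noise-free.  The output is bit-for-bit reproducible from the
#' configuration seed.
#'
#' @param config A [phantom_config()].
#' @param protocol A [scan_protocol()].
#' @param psis Distinct RF phase increments in degrees.
#' @return A [phase_cycled_set()].
#' @export
render_phase_cycled_cine <- function(config, protocol, psis) {
  stopifnot(inherits(config, "phantom_config"),
            inherits(protocol, "scan_protocol"))
  if (!length(psis)) stop("render_phase_cycled_cine: psis must be non-empty")
  if (anyDuplicated(psis))
    stop("render_phase_cycled_cine: duplicate psi values")
  ny <- config$grid[1]; nx <- config$grid[2]; nf <- config$n_frames
  b0 <- make_b0_map(config)
  fd <- temporal_resolution_ms(protocol)

  flow_masks <- lapply(config$flow_regions, function(fr)
    ellipse_mask(config$grid, fr$center, fr$axes, fr$angle_deg %||% 0))

  render_movie <- function(psi, reference = FALSE) {
    arr <- array(0, c(nf, ny, nx))
    # per-voxel transient echoes are frame-independent; compute once
    flow_sig <- lapply(seq_along(config$flow_regions), function(i) {
      fr <- config$flow_regions[[i]]
      ts <- fr$flow$tissue
      df <- if (reference) rep(0, sum(flow_masks[[i]])) else b0[flow_masks[[i]]]
      if (reference) {
        ss <- Mod(ss_signal_vec(ts$t1_ms, ts$t2_ms, ts$rho, df,
                                protocol$tr_ms, protocol$te_ms,
                                protocol$flip_deg, 180))
        list(stationary = ss)
      } else {
        ss <- Mod(ss_signal_vec(ts$t1_ms, ts$t2_ms, ts$rho, df,
                                protocol$tr_ms, protocol$te_ms,
                                protocol$flip_deg, psi))
        v <- abs(fr$flow$velocity_mm_s)
        tr_s <- protocol$tr_ms / 1000
        n_dwell <- ifelse(v > 0,
                          pmax(1, round(fr$flow$slice_thickness_mm / (v * tr_s))),
                          Inf)
        n_cap <- ceiling(5 * ts$t1_ms / protocol$tr_ms)
        n_sim <- min(max(c(1, n_dwell[is.finite(n_dwell)])), n_cap)
        em <- Mod(bloch_transient_vec(ts$t1_ms, ts$t2_ms, ts$rho, df,
                                      protocol$tr_ms, protocol$te_ms,
                                      protocol$flip_deg, psi, n_sim))
        em <- matrix(em, nrow = n_sim)
        list(ss = ss, echo_mag = em, n_dwell = n_dwell)
      }
    })
    for (f in seq_len(nf)) {
      img <- render_frame(config, protocol, psi, f,
                          if (reference) NULL else b0)
      for (i in seq_along(config$flow_regions)) {
        fs <- flow_sig[[i]]
        if (reference) {
          img[flow_masks[[i]]] <- fs$stationary
        } else {
          n <- fs$n_dwell[(f - 1) %% length(fs$n_dwell) + 1]
          img[flow_masks[[i]]] <- if (!is.finite(n)) fs$ss else {
            n_sim <- nrow(fs$echo_mag)
            if (n <= n_sim) colMeans(fs$echo_mag[seq_len(n), , drop = FALSE])
            else (colSums(fs$echo_mag) + (n - n_sim) * fs$ss) / n
          }
        }
      }
      arr[f, , ] <- img
    }
    arr
  }

  ref_arr <- render_movie(NA, reference = TRUE)
  peak <- max(ref_arr)
  sigma <- config$noise_sigma * peak

  set.seed(config$seed)
  movies <- lapply(psis, function(psi) {
    arr <- render_movie(psi)
    if (sigma > 0) {
      n1 <- array(rnorm(length(arr), sd = sigma), dim(arr))
      n2 <- array(rnorm(length(arr), sd = sigma), dim(arr))
      arr <- sqrt((arr + n1)^2 + n2^2)
    }
    cine_movie(arr, psi_deg = psi, tr_ms = protocol$tr_ms,
               te_ms = protocol$te_ms, flip_deg = protocol$flip_deg,
               frame_duration_ms = fd)
  })
  reference <- cine_movie(ref_arr, psi_deg = NA, tr_ms = protocol$tr_ms,
                          te_ms = protocol$te_ms, flip_deg = protocol$flip_deg,
                          frame_duration_ms = fd, label = "reference")
  masks <- lapply(names(config$masks), function(nm) {
    sp <- config$masks[[nm]]
    roi_mask(ellipse_mask(config$grid, sp$center, sp$axes,
                          sp$angle_deg %||% 0), label = nm)
  })
  names(masks) <- names(config$masks)
  phase_cycled_set(movies, reference = reference, masks = masks,
                   protocol = protocol)
}

# 3 T tissue table used by the presets
preset_tissues <- function() {
  list(blood = tissue_params(1900, 250, rho = 1.0),
       myocardium = tissue_params(1470, 47, rho = 0.8),
       muscle = tissue_params(1400, 40, rho = 0.6),
       fat = tissue_params(380, 130, rho = 0.9))
}

#' Built-in phantom scenes
#'
#' `lv_short_axis` emulates a mid-ventricular short-axis slice: torso,
#' left-ventricular myocardium and cavity, right-ventricular cavity, a
#' fatty liver wedge, and a pulsatile descending aorta as flow region,
#' with a focal off-resonance gradient over the heart.  `la_view` emulates
#' a left-atrial view where a strong, wide focal off-resonance centered on
#' the atrial blood pool drives a large-area signal void at a 180-degree
#' RF phase increment; a pulmonary-vein ostium with inflow is included.
#'
#' @param preset `"lv_short_axis"` or `"la_view"`.
#' @param grid `c(rows, cols)` of the rendered scene.
#' @param n_frames Number of cardiac phases.
#' @param seed Noise seed stored in the configuration.
#' @return A list with elements `config` ([phantom_config()]) and
#'   `protocol` ([scan_protocol()]).
#' @examples
#' sc <- make_default_scene("lv_short_axis", grid = c(48, 48), n_frames = 6)
#' set <- render_phase_cycled_cine(sc$config, sc$protocol, c(90, 270))
#' @export
make_default_scene <- function(preset = c("lv_short_axis", "la_view"),
                               grid = c(128, 128), n_frames = 12, seed = 1) {
  preset <- match.arg(preset)
  ts <- preset_tissues()
  protocol <- scan_protocol(tr_ms = 2.98, te_ms = 1.37, flip_deg = 60,
                            views_per_segment = 24,
                            n_cardiac_phases = n_frames, n_movies = 2,
                            phase_increments_deg = c(90, 270))
  nf <- n_frames
  half_tr_hz <- 1000 / (2 * protocol$tr_ms)   # null spacing, ~167.8 Hz
  if (preset == "lv_short_axis") {
    aorta_v <- 80 + 520 * pmax(0, sin(2 * pi * (seq_len(nf) - 1) / nf))^2
    config <- phantom_config(
      grid = grid, n_frames = nf,
      regions = list(
        list(center = c(0.50, 0.50), axes = c(0.46, 0.48), tissue = ts$muscle,
             contract = 0),
        list(center = c(0.78, 0.30), axes = c(0.14, 0.18), tissue = ts$fat,
             contract = 0),
        list(center = c(0.45, 0.42), axes = c(0.17, 0.17),
             tissue = ts$myocardium, contract = 0.06),
        list(center = c(0.45, 0.42), axes = c(0.11, 0.11), tissue = ts$blood,
             contract = 0.28),
        list(center = c(0.40, 0.64), axes = c(0.10, 0.12), tissue = ts$blood,
             contract = 0.20)),
      b0 = list(poly = c(20, 10, 30, 0, 0, 0),
                focal_amp_hz = 140, focal_center = c(0.45, 0.42),
                focal_width = 0.16),
      flow_regions = list(
        list(center = c(0.80, 0.56), axes = c(0.045, 0.045),
             flow = flow_spec(aorta_v, slice_thickness_mm = 8,
                              tissue = ts$blood))),
      noise_sigma = 0.02,
      masks = list(heart = list(center = c(0.44, 0.47), axes = c(0.20, 0.24)),
                   flow = list(center = c(0.80, 0.56), axes = c(0.036, 0.036))),
      seed = seed)
  } else {
    pv_v <- 120 + 280 * pmax(0, sin(2 * pi * (seq_len(nf) - 1) / nf))^2
    config <- phantom_config(
      grid = grid, n_frames = nf,
      regions = list(
        list(center = c(0.50, 0.50), axes = c(0.46, 0.48), tissue = ts$muscle,
             contract = 0),
        list(center = c(0.48, 0.50), axes = c(0.25, 0.29),
             tissue = ts$myocardium, contract = 0.04),
        list(center = c(0.48, 0.50), axes = c(0.20, 0.24), tissue = ts$blood,
             contract = 0.10),
        list(center = c(0.20, 0.64), axes = c(0.06, 0.06), tissue = ts$blood,
             contract = 0)),
      b0 = list(poly = c(10, 0, 15, 0, 0, 0),
                focal_amp_hz = 1.1 * half_tr_hz, focal_center = c(0.45, 0.52),
                focal_width = 0.28),
      flow_regions = list(
        list(center = c(0.20, 0.64), axes = c(0.05, 0.05),
             flow = flow_spec(pv_v, slice_thickness_mm = 8,
                              tissue = ts$blood))),
      noise_sigma = 0.02,
      masks = list(
        heart = list(center = c(0.48, 0.50), axes = c(0.27, 0.31)),
        la_cavity = list(center = c(0.48, 0.50), axes = c(0.15, 0.18)),
        pv_ostium = list(center = c(0.20, 0.64), axes = c(0.042, 0.042))),
      seed = seed)
  }
  list(config = config, protocol = protocol)
}

#' Randomized variant of a preset scene
#'
#' Jitters geometry, off-resonance field, noise level and flow velocity
#' around the preset values, keeping the focal off-resonance gradient
#' over the heart so banding crosses the heart ROI.  Used to build
#' training/validation datasets of distinct but comparable scenes.
#'
#' @inheritParams make_default_scene
#' @param seed Seed controlling both the parameter jitter and the
#'   rendered noise.
#' @return A list with elements `config` and `protocol`.
#' @export
sample_scene <- function(preset = "lv_short_axis", seed = 1,
                         grid = c(128, 128), n_frames = 12) {
  sc <- make_default_scene(preset, grid = grid, n_frames = n_frames,
                           seed = seed)
  set.seed(seed)
  cfg <- sc$config
  for (i in seq_along(cfg$regions)) {
    cfg$regions[[i]]$center <- cfg$regions[[i]]$center + runif(2, -0.03, 0.03)
    cfg$regions[[i]]$axes <- cfg$regions[[i]]$axes * runif(1, 0.85, 1.15)
    cfg$regions[[i]]$contract <-
      (cfg$regions[[i]]$contract %||% 0) * runif(1, 0.8, 1.2)
  }
  heart_center <- cfg$regions[[3]]$center
  cfg$b0$poly[1:3] <- c(runif(1, -30, 30), runif(1, -40, 40),
                        runif(1, -40, 40))
  cfg$b0$focal_amp_hz <- runif(1, 90, 190) * sample(c(-1, 1), 1)
  cfg$b0$focal_center <- heart_center + runif(2, -0.05, 0.05)
  cfg$b0$focal_width <- runif(1, 0.13, 0.22)
  cfg$noise_sigma <- runif(1, 0.015, 0.03)
  for (i in seq_along(cfg$flow_regions)) {
    cfg$flow_regions[[i]]$flow$velocity_mm_s <-
      cfg$flow_regions[[i]]$flow$velocity_mm_s * runif(1, 0.7, 1.3)
  }
  # keep the ROI masks tracking the jittered anatomy
  if (preset == "lv_short_axis") {
    cfg$masks$heart$center <- heart_center + c(-0.01, 0.05)
    cfg$masks$flow$center <- cfg$flow_regions[[1]]$center
  }
  cfg$seed <- seed
  list(config = cfg, protocol = sc$protocol)
}
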