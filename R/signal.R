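#' Tissue relaxation parameters
#'
#' @param t1_ms Longitudinal relaxation time in ms (must be >= `t2_ms`).
#' @param t2_ms Transverse relaxation time in ms (positive).
#' @param rho Proton density, arbitrary non-negative units.
#' @param df_hz Off-resonance frequency in Hz.
#' @return An object of class `tissue_params`.
#' @examples
#' myocardium <- tissue_params(1470, 47, rho = 0.8)
#' @export
tissue_params <- function(t1_ms, t2_ms, rho = 1, df_hz = 0) {
  if (!(t2_ms > 0) || !(t1_ms >= t2_ms))
    stop("tissue_params: need t1_ms >= t2_ms > 0")
  if (rho < 0) stop("tissue_params: rho must be non-negative")
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, rho = rho, df_hz = df_hz),
            class = "tissue_params")
}

#' Through-plane flow description
#'
#' Plug flow of fresh spins through the imaging slice.  The per-frame
#' velocity waveform has one entry per cardiac phase; spins flowing at
#' velocity v spend about `slice_thickness_mm / (v * TR)` repetitions in
#' the slice, never reaching the steady state.
#'
#' @param velocity_mm_s Per-frame through-plane velocity waveform in mm/s.
#' @param slice_thickness_mm Slice thickness in mm (positive).
#' @param tissue [tissue_params()] of the flowing spins.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(velocity_mm_s, slice_thickness_mm = 8,
                      tissue = tissue_params(1900, 250)) {
  if (!(slice_thickness_mm > 0)) stop("flow_spec: slice thickness must be > 0")
  stopifnot(inherits(tissue, "tissue_params"))
  structure(list(velocity_mm_s = as.numeric(velocity_mm_s),
                 slice_thickness_mm = slice_thickness_mm, tissue = tissue),
            class = "flow_spec")
}

# vectorized closed-form steady state over off-resonance df (Hz)
ss_signal_vec <- function(t1, t2, rho, df_hz, tr_ms, te_ms, flip_deg, psi_deg) {
  E1 <- exp(-tr_ms / t1); E2 <- exp(-tr_ms / t2)
  a <- flip_deg * pi / 180
  phi <- 2 * pi * df_hz * tr_ms / 1000
  th <- phi - psi_deg * pi / 180
  D <- (1 - E1 * cos(a)) * (1 - E2 * cos(th)) -
    E2 * (E1 - cos(a)) * (E2 - cos(th))
  rho * (1 - E1) * sin(a) * (1 - E2 * exp(-1i * th)) / D *
    exp(1i * phi * te_ms / tr_ms) * exp(-te_ms / t2)
}

#' Closed-form bSSFP steady-state signal
#'
#' Transverse magnetization at the echo time of a balanced SSFP sequence
#' in steady state, as a function of tissue relaxation, sequence timing,
#' and the RF phase increment.  With per-TR precession
#' `phi = 2*pi*df*TR` and `theta = phi - psi`, the magnitude null (dark
#' band) sits at `theta = 0` modulo a full cycle, so increasing the RF
#' phase increment rigidly translates the banding profile in frequency.
#'
#' @param tissue [tissue_params()].
#' @param protocol [scan_protocol()] supplying TR, TE and flip angle.
#' @param psi_deg RF phase increment in degrees.
#' @param df_hz Off-resonance in Hz; defaults to `tissue$df_hz`.  May be a
#'   vector, in which case a complex vector is returned.
#' @return Complex transverse magnetization at TE.
#' @examples
#' p <- scan_protocol()
#' Mod(ssfp_steady_state(tissue_params(1000, 200), p, psi_deg = 180))
#' @export
ssfp_steady_state <- function(tissue, protocol, psi_deg,
                              df_hz = tissue$df_hz) {
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(protocol, "scan_protocol"))
  ss_signal_vec(tissue$t1_ms, tissue$t2_ms, tissue$rho, df_hz,
                protocol$tr_ms, protocol$te_ms, protocol$flip_deg, psi_deg)
}

# vectorized transient over a vector of off-resonance values; returns a
# n_tr x length(df_hz) complex matrix of demodulated echoes at TE.
bloch_transient_vec <- function(t1, t2, rho, df_hz, tr_ms, te_ms, flip_deg,
                                psi_deg, n_tr, m_init = NULL) {
  a <- flip_deg * pi / 180
  psi <- psi_deg * pi / 180
  nv <- length(df_hz)
  phi_te <- 2 * pi * df_hz * te_ms / 1000
  phi_rest <- 2 * pi * df_hz * (tr_ms - te_ms) / 1000
  rot_te <- exp(1i * phi_te); rot_rest <- exp(1i * phi_rest)
  E2te <- exp(-te_ms / t2); E1te <- exp(-te_ms / t1)
  E2r <- exp(-(tr_ms - te_ms) / t2); E1r <- exp(-(tr_ms - te_ms) / t1)
  ca <- cos(a); sa <- sin(a)
  mxy <- complex(real = rep(0, nv), imaginary = rep(0, nv))
  mz <- rep(rho, nv)
  if (!is.null(m_init)) {
    mxy <- rep_len(complex(real = m_init[1], imaginary = m_init[2]), nv)
    mz <- rep_len(m_init[3], nv)
  }
  echoes <- matrix(0i, n_tr, nv)
  for (n in seq_len(n_tr)) {
    # alpha pulse about an in-plane axis with azimuth (n-1)*psi:
    # Rz(Phi) Rx(a) Rz(-Phi), right-handed
    ephi <- exp(1i * (n - 1) * psi)
    u <- mxy * Conj(ephi)                       # into the pulse frame
    ur <- Re(u); ui <- Im(u)
    ui2 <- ca * ui - sa * mz
    mz <- sa * ui + ca * mz
    mxy <- complex(real = ur, imaginary = ui2) * ephi
    # free precession + relaxation to TE, demodulated echo
    mxy <- mxy * rot_te * E2te
    mz <- rho * (1 - E1te) + mz * E1te
    echoes[n, ] <- 1i * mxy * Conj(ephi)
    # remainder of the TR
    mxy <- mxy * rot_rest * E2r
    mz <- rho * (1 - E1r) + mz * E1r
  }
  echoes
}

#' Brute-force Bloch transient of phase-cycled bSSFP
#'
#' Iterates the per-TR recursion -- an alpha pulse about an axis whose
#' azimuth advances by `psi_deg` every TR, free precession at the tissue
#' off-resonance, and T1/T2 relaxation toward thermal equilibrium -- and
#' returns the demodulated transverse signal at the echo time of every
#' repetition.  The sequence of echoes converges to
#' [ssfp_steady_state()]; the early oscillatory echoes are what flowing
#' spins that recently entered the slice contribute (flow artifacts).
#'
#' @param tissue [tissue_params()].
#' @param protocol [scan_protocol()].
#' @param psi_deg RF phase increment in degrees.
#' @param n_tr Number of repetitions to simulate (>= 1).
#' @param m_init Initial magnetization as `c(mx, my, mz)`; defaults to
#'   thermal equilibrium `c(0, 0, rho)`.
#' @return Complex vector of `n_tr` echo signals.
#' @examples
#' p <- scan_protocol()
#' e <- bloch_transient(tissue_params(1000, 200), p, 180, n_tr = 3000)
#' Mod(e[3000] - ssfp_steady_state(tissue_params(1000, 200), p, 180))
#' @export
bloch_transient <- function(tissue, protocol, psi_deg, n_tr,
                            m_init = c(0, 0, tissue$rho)) {
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(protocol, "scan_protocol"))
  if (length(n_tr) != 1 || !is.finite(n_tr) || n_tr < 1)
    stop("bloch_transient: n_tr must be >= 1")
  as.vector(bloch_transient_vec(tissue$t1_ms, tissue$t2_ms, tissue$rho,
                                tissue$df_hz, protocol$tr_ms, protocol$te_ms,
                                protocol$flip_deg, psi_deg, as.integer(n_tr),
                                m_init))
}

# mean magnitude over the first n echoes, padding the tail with the
# steady-state magnitude beyond the simulated transient
inflow_mean_mag <- function(echo_mag, n, ss_mag) {
  n_sim <- length(echo_mag)
  if (n <= n_sim) return(mean(echo_mag[seq_len(n)]))
  (sum(echo_mag) + (n - n_sim) * ss_mag) / n
}

#' Through-plane inflow signal
#'
#' Magnitude signal of a voxel fed by plug flow through the slice.  At
#' frame `f`, spins dwell for about
#' `n = slice_thickness / (|v(f)| * TR)` repetitions; the voxel contains
#' cohorts that entered 1, 2, ..., n TRs ago, so its signal is the mean
#' transient echo magnitude over the first `n` echoes (started from
#' thermal equilibrium).  Near a banding null the early echoes exceed the
#' steady state, producing the hyperintense, time-varying flow artifact;
#' at zero velocity the stationary steady-state magnitude is returned.
#'
#' @param flow [flow_spec()].
#' @param protocol [scan_protocol()].
#' @param psi_deg RF phase increment in degrees.
#' @param df_hz Off-resonance in Hz; defaults to the flowing tissue's.
#' @return Numeric vector of per-frame magnitudes (one per velocity entry).
#' @export
inflow_signal <- function(flow, protocol, psi_deg, df_hz = flow$tissue$df_hz) {
  stopifnot(inherits(flow, "flow_spec"), inherits(protocol, "scan_protocol"))
  ts <- flow$tissue
  ss_mag <- Mod(ss_signal_vec(ts$t1_ms, ts$t2_ms, ts$rho, df_hz,
                              protocol$tr_ms, protocol$te_ms,
                              protocol$flip_deg, psi_deg))
  v <- abs(flow$velocity_mm_s)
  tr_s <- protocol$tr_ms / 1000
  n_dwell <- ifelse(v > 0,
                    pmax(1, round(flow$slice_thickness_mm / (v * tr_s))),
                    Inf)
  n_cap <- ceiling(5 * ts$t1_ms / protocol$tr_ms)
  finite <- is.finite(n_dwell)
  if (!any(finite)) return(rep(ss_mag, length(v)))
  n_sim <- min(max(n_dwell[finite]), n_cap)
  echo_mag <- Mod(bloch_transient_vec(ts$t1_ms, ts$t2_ms, ts$rho, df_hz,
                                      protocol$tr_ms, protocol$te_ms,
                                      protocol$flip_deg, psi_deg, n_sim))
  vapply(n_dwell, function(n) {
    if (!is.finite(n)) return(ss_mag)
    inflow_mean_mag(echo_mag, n, ss_mag)
  }, numeric(1))
}

#' Off-resonance frequency of the banding null
#'
#' The magnitude minimum of the bSSFP profile occurs where the per-TR
#' precession matches the RF phase increment (`theta = 0`), i.e. at
#' `df = psi / (360 * TR)` modulo `1/TR`.  Nulls of `psi` and
#' `psi + 180` are therefore offset by exactly `1/(2 TR)` Hz.
#'
#' @param protocol [scan_protocol()].
#' @param psi_deg RF phase increment in degrees.
#' @return Frequency of the null in Hz, in `[0, 1/TR)`.
#' @export
band_null_offset <- function(protocol, psi_deg) {
  stopifnot(inherits(protocol, "scan_protocol"))
  tr_s <- protocol$tr_ms / 1000
  ((psi_deg / 360) / tr_s) %% (1 / tr_s)
}
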