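#' Scan protocol for (phase-cycled) bSSFP cine
#'
#' Describes the sequence timing and segmentation of a retrospectively
#' gated, segmented bSSFP cine acquisition: repetition/echo time, flip
#' angle, views per segment, number of reconstructed cardiac phases, and
#' the per-movie heartbeat budget (dummy beats to approach steady state
#' plus imaging beats).  A twofold protocol carries two RF phase
#' increments exactly half a cycle (180 degrees) apart.
#'
#' @param tr_ms Repetition time in milliseconds (must exceed `te_ms`).
#' @param te_ms Echo time in milliseconds (positive).
#' @param flip_deg Flip angle in degrees, in (0, 90].
#' @param views_per_segment k-space lines acquired per heartbeat per
#'   cardiac phase; `views_per_segment * tr_ms` is the temporal resolution.
#' @param n_cardiac_phases Number of reconstructed cardiac phases.
#' @param n_movies Number of sequentially acquired movies (2 for twofold).
#' @param dummy_beats_per_movie Un-sampled steady-state preparation beats.
#' @param imaging_beats_per_movie Sampled heartbeats per movie.
#' @param phase_increments_deg RF phase increments in degrees, each in
#'   (0, 360].  For a twofold protocol the two must differ by 180 mod 360.
#'
#' @return An object of class `scan_protocol`.
#' @examples
#' p <- scan_protocol(tr_ms = 2.98, te_ms = 1.37, flip_deg = 60,
#'                    views_per_segment = 24, phase_increments_deg = c(90, 270))
#' temporal_resolution_ms(p)
#' scan_duration_beats(p)
#' @export
scan_protocol <- function(tr_ms = 2.98, te_ms = 1.37, flip_deg = 60,
                          views_per_segment = 24, n_cardiac_phases = 25,
                          n_movies = 2, dummy_beats_per_movie = 1,
                          imaging_beats_per_movie = 5,
                          phase_increments_deg = c(90, 270)) {
  stopifnot(is.numeric(tr_ms), is.numeric(te_ms), is.numeric(flip_deg))
  if (!(tr_ms > te_ms && te_ms > 0))
    stop("scan_protocol: need tr_ms > te_ms > 0")
  if (!(flip_deg > 0 && flip_deg <= 90))
    stop("scan_protocol: flip_deg must lie in (0, 90]")
  if (views_per_segment < 1 || n_cardiac_phases < 1)
    stop("scan_protocol: counts must be positive")
  if (n_movies < 0 || dummy_beats_per_movie < 0 || imaging_beats_per_movie < 0)
    stop("scan_protocol: beat counts must be non-negative")
  psis <- as.numeric(phase_increments_deg)
  if (length(psis) && (any(psis <= 0) || any(psis > 360)))
    stop("scan_protocol: phase increments must lie in (0, 360]")
  if (n_movies == 2 && length(psis) == 2) {
    d <- (psis[2] - psis[1]) %% 360
    if (abs(d - 180) > 1e-9)
      stop("scan_protocol: twofold increments must be 180 degrees apart (got ",
           d, ")")
  }
  structure(list(tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
                 views_per_segment = as.integer(views_per_segment),
                 n_cardiac_phases = as.integer(n_cardiac_phases),
                 n_movies = as.integer(n_movies),
                 dummy_beats_per_movie = as.integer(dummy_beats_per_movie),
                 imaging_beats_per_movie = as.integer(imaging_beats_per_movie),
                 phase_increments_deg = psis),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat("bSSFP scan protocol\n")
  cat(sprintf("  TR/TE %.2f/%.2f ms, flip %g deg, VPS %d, %d cardiac phases\n",
              x$tr_ms, x$te_ms, x$flip_deg, x$views_per_segment,
              x$n_cardiac_phases))
  cat(sprintf("  %d movie(s) x (%d dummy + %d imaging) heartbeats; psi = {%s} deg\n",
              x$n_movies, x$dummy_beats_per_movie, x$imaging_beats_per_movie,
              paste(x$phase_increments_deg, collapse = ", ")))
  invisible(x)
}

#' Uniform RF phase-increment schedule
#'
#' Returns the uniformly spaced schedule `360 * n / n_increments` for
#' `n = 1, ..., n_increments`, i.e. increments in (0, 360] with the last
#' equal to 360 (equivalent to 0 modulo a full cycle).
#'
#' @param n_increments Positive number of increments.
#' @return Numeric vector of increments in degrees.
#' @examples
#' phase_schedule(12)   # 30-degree spacing, psi_3 = 90, psi_12 = 360
#' @export
phase_schedule <- function(n_increments) {
  if (length(n_increments) != 1 || !is.finite(n_increments) || n_increments < 1)
    stop("phase_schedule: n_increments must be a positive count")
  n_increments <- as.integer(n_increments)
  360 * seq_len(n_increments) / n_increments
}

#' Enumerate training pairs of phase-cycled movies
#'
#' Forms, for each slice-set (one slice of one subject scanned at all
#' increments), every ordered pair of distinct increments whose offset
#' `(psi_j - psi_i) mod 360` belongs to `offsets`.  Pairs at an offset of
#' exactly 180 degrees are deduplicated to unordered pairs, because an
#' order-invariant (symmetrized) network makes the two orderings of an
#' opposite-phase pair redundant; other offsets are counted in both orders.
#'
#' @param increments Uniformly spaced increments in degrees (see
#'   [phase_schedule()]).
#' @param offsets Offsets of interest in degrees; each must be a multiple
#'   of the increment spacing.
#' @param n_slice_sets Number of slice-sets over which pairs are replicated.
#' @return A list with `pairs` (data frame of `slice_set`, `psi_1`, `psi_2`,
#'   `offset_deg`), `counts` (named vector of pair counts per offset) and
#'   `total`.
#' @examples
#' enumerate_training_pairs(phase_schedule(12), c(90, 180, 270), 54)$total
#' @export
enumerate_training_pairs <- function(increments, offsets, n_slice_sets = 1) {
  increments <- sort(as.numeric(increments))
  if (length(increments) > 1) {
    sp <- diff(increments)
    if (max(abs(sp - sp[1])) > 1e-9)
      stop("enumerate_training_pairs: increments must be uniformly spaced")
    spacing <- sp[1]
    bad <- offsets[abs(offsets / spacing - round(offsets / spacing)) > 1e-9]
    if (length(bad))
      stop("enumerate_training_pairs: offsets not a multiple of the ",
           spacing, "-degree spacing: ", paste(bad, collapse = ", "))
  }
  if (n_slice_sets < 0) stop("enumerate_training_pairs: negative slice-set count")
  offsets <- as.numeric(offsets)

  one <- NULL
  n <- length(increments)
  if (n >= 2) {
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx <- idx[idx$i != idx$j, ]
    off <- (increments[idx$j] - increments[idx$i]) %% 360
    keep <- off %in% offsets
    idx <- idx[keep, ]; off <- off[keep]
    # opposite-phase pairs: keep one ordering only
    drop <- abs(off - 180) < 1e-9 & idx$i > idx$j
    idx <- idx[!drop, ]; off <- off[!drop]
    if (nrow(idx))
      one <- data.frame(psi_1 = increments[idx$i], psi_2 = increments[idx$j],
                        offset_deg = off)
  }
  if (is.null(one) || n_slice_sets == 0) {
    pairs <- data.frame(slice_set = integer(), psi_1 = numeric(),
                        psi_2 = numeric(), offset_deg = numeric())
  } else {
    pairs <- do.call(rbind, lapply(seq_len(n_slice_sets), function(s)
      cbind(slice_set = s, one)))
  }
  counts <- vapply(offsets, function(d) sum(pairs$offset_deg == d), numeric(1))
  names(counts) <- as.character(offsets)
  list(pairs = pairs, counts = counts, total = nrow(pairs))
}

#' Total heartbeat count of the sequence
#'
#' Each movie costs its dummy (steady-state preparation) beats plus its
#' imaging beats; movies are acquired back to back in one breath-hold.
#'
#' @param protocol A [scan_protocol()].
#' @return Heartbeat count (integer).
#' @export
scan_duration_beats <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  protocol$n_movies *
    (protocol$dummy_beats_per_movie + protocol$imaging_beats_per_movie)
}

#' Temporal resolution of a segmented cine
#'
#' @param protocol A [scan_protocol()].
#' @return `views_per_segment * tr_ms`, in milliseconds.
#' @export
temporal_resolution_ms <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  protocol$views_per_segment * protocol$tr_ms
}

#' Write / read a scan protocol JSON sidecar
#'
#' @param protocol A [scan_protocol()].
#' @param path File path of the JSON sidecar.
#' @return `read_protocol_json` returns a [scan_protocol()];
#'   `write_protocol_json` invisibly returns `path`.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "scan_protocol"))
  atomic_write(path, function(tmp)
    jsonlite::write_json(unclass(protocol), tmp, auto_unbox = TRUE,
                         digits = NA))
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scan_protocol, x[intersect(names(x), names(formals(scan_protocol)))])
}
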