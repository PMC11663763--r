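# all file writes go through a temp-file + rename so interrupted runs
# never leave truncated outputs
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- file.path(dirname(path),
                   paste0(".tmp-", Sys.getpid(), "-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("atomic write failed for ", path)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read / write a cine movie as NIfTI with a JSON sidecar
#'
#' Movies are stored as 32-bit float NIfTI with axes (x, y, t); in
#' memory the array is (t, y, x).  Acquisition metadata (RF phase
#' increment, TR, TE, flip angle, frame duration) travels in a JSON
#' sidecar next to the image file; a missing sidecar on read yields
#' default (`NA`) metadata with a warning.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param movie A [cine_movie()] (for writing).
#' @return `read_cine` returns a [cine_movie()]; `write_cine` invisibly
#'   returns `path`.
#' @export
read_cine <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- array(img, d[1:3])
    d <- dim(img)
  }
  if (length(d) != 3)
    stop("read_cine: expected a 3D (x, y, t) volume, got ", length(d),
         " axes in ", path)
  data <- aperm(array(as.numeric(img), d), c(3, 2, 1))
  meta <- list(psi_deg = NA_real_, tr_ms = NA_real_, te_ms = NA_real_,
               flip_deg = NA_real_, frame_duration_ms = NA_real_,
               combined_from = NULL, label = NULL)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    js <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta[names(js)[names(js) %in% names(meta)]] <-
      js[names(js) %in% names(meta)]
  } else {
    warning("read_cine: no sidecar for ", path, "; default metadata used")
  }
  cine_movie(pmax(data, 0), psi_deg = as.numeric(meta$psi_deg),
             tr_ms = as.numeric(meta$tr_ms), te_ms = as.numeric(meta$te_ms),
             flip_deg = as.numeric(meta$flip_deg),
             frame_duration_ms = as.numeric(meta$frame_duration_ms),
             combined_from = meta$combined_from, label = meta$label)
}

#' @rdname read_cine
#' @export
write_cine <- function(movie, path) {
  stopifnot(inherits(movie, "cine_movie"))
  arr <- aperm(movie$data, c(3, 2, 1))
  atomic_write(path, function(tmp)
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), tmp))
  meta <- movie[c("psi_deg", "tr_ms", "te_ms", "flip_deg",
                  "frame_duration_ms", "combined_from", "label")]
  meta <- meta[!vapply(meta, function(x) is.null(x) ||
                         all(is.na(x)), logical(1))]
  atomic_write(sidecar_path(path), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null"))
  invisible(path)
}

#' Read / write an ROI mask as NIfTI
#'
#' @param mask A [roi_mask()] (for writing).
#' @param path NIfTI file path; stored as (x, y) with values 0/1.
#' @param label ROI label to attach on read.
#' @return `read_mask` returns a [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  arr <- t(mask$data) * 1
  atomic_write(path, function(tmp)
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), tmp))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, label = "roi") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 3 && d[3] == 1) { img <- array(img, d[1:2]); d <- dim(img) }
  if (length(d) != 2)
    stop("read_mask: expected a 2D mask, got ", length(d), " axes")
  roi_mask(t(array(as.numeric(img), d)) > 0.5, label = label)
}

#' Write a rendered phase-cycled set to a directory
#'
#' Writes each movie (`psi_<psi>.nii.gz` + sidecar), the reference, the
#' masks, the protocol sidecar and a `manifest.json` listing them all.
#'
#' @param set A [phase_cycled_set()].
#' @param dir Output directory (created if needed).
#' @param preset,seed Provenance recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_set_dir <- function(set, dir, preset = NA, seed = NA) {
  stopifnot(inherits(set, "phase_cycled_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  movies <- lapply(names(set$movies), function(psi) {
    fn <- paste0("psi_", psi, ".nii.gz")
    write_cine(set$movies[[psi]], file.path(dir, fn))
    list(psi_deg = as.numeric(psi), path = fn, sidecar = sidecar_path(fn))
  })
  ref <- NULL
  if (!is.null(set$reference)) {
    write_cine(set$reference, file.path(dir, "reference.nii.gz"))
    ref <- "reference.nii.gz"
  }
  masks <- lapply(names(set$masks), function(nm) {
    fn <- paste0("mask_", nm, ".nii.gz")
    write_mask(set$masks[[nm]], file.path(dir, fn))
    fn
  })
  names(masks) <- names(set$masks)
  if (!is.null(set$protocol))
    write_protocol_json(set$protocol, file.path(dir, "protocol.json"))
  manifest <- list(schema_version = 1, preset = preset, seed = seed,
                   movies = movies, reference = ref, masks = masks,
                   protocol = if (is.null(set$protocol)) NULL else
                     "protocol.json")
  atomic_write(file.path(dir, "manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null"))
  invisible(file.path(dir, "manifest.json"))
}

#' Load a phase-cycled set from a manifest directory
#'
#' @param dir Directory containing `manifest.json` (as written by
#'   [write_set_dir()]).
#' @return A [phase_cycled_set()].
#' @export
read_set_dir <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("read_set_dir: no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path)
  paths <- c(vapply(mf$movies, function(m) m$path, character(1)),
             unlist(mf$masks), mf$reference, mf$protocol)
  missing_files <- paths[!file.exists(file.path(dir, paths))]
  if (length(missing_files))
    stop("read_set_dir: manifest references missing files: ",
         paste(missing_files, collapse = ", "))
  movies <- lapply(mf$movies, function(m)
    read_cine(file.path(dir, m$path)))
  reference <- if (!is.null(mf$reference))
    read_cine(file.path(dir, mf$reference)) else NULL
  masks <- lapply(names(mf$masks), function(nm)
    read_mask(file.path(dir, mf$masks[[nm]]), label = nm))
  names(masks) <- names(mf$masks)
  protocol <- if (!is.null(mf$protocol))
    read_protocol_json(file.path(dir, mf$protocol)) else NULL
  phase_cycled_set(movies, reference = reference, masks = masks,
                   protocol = protocol)
}

#' Read a simulator scene configuration from YAML
#'
#' Builds a ([phantom_config()], [scan_protocol()]) pair from a YAML file
#' with top-level keys `protocol` (fields of [scan_protocol()]) and
#' `phantom` (fields of [phantom_config()], with `tissue` sub-maps given
#' as `t1_ms`/`t2_ms`/`rho`/`df_hz` and flow regions carrying a `flow`
#' sub-map with `velocity_mm_s`, `slice_thickness_mm` and `tissue`).
#' Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return A list with elements `config` and `protocol`, as returned by
#'   [make_default_scene()].
#' @export
read_scene_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_scene_yaml needs the 'yaml' package")
  doc <- yaml::read_yaml(path)
  proto <- do.call(scan_protocol, doc$protocol %||% list())
  ph <- doc$phantom %||% list()
  as_tissue <- function(x) do.call(tissue_params, x)
  regions <- lapply(ph$regions %||% list(), function(rg) {
    rg$tissue <- as_tissue(rg$tissue)
    rg$center <- as.numeric(rg$center); rg$axes <- as.numeric(rg$axes)
    rg
  })
  flow_regions <- lapply(ph$flow_regions %||% list(), function(fr) {
    ts <- as_tissue(fr$flow$tissue %||%
                      list(t1_ms = 1900, t2_ms = 250))
    fr$flow <- flow_spec(as.numeric(fr$flow$velocity_mm_s),
                         fr$flow$slice_thickness_mm %||% 8, tissue = ts)
    fr$center <- as.numeric(fr$center); fr$axes <- as.numeric(fr$axes)
    fr
  })
  config <- phantom_config(
    grid = as.integer(ph$grid %||% c(128, 128)),
    n_frames = ph$n_frames %||% 12,
    regions = regions,
    b0 = utils::modifyList(list(poly = rep(0, 6), focal_amp_hz = 0,
                                focal_center = c(0.5, 0.5),
                                focal_width = 0.15), ph$b0 %||% list()),
    flow_regions = flow_regions,
    noise_sigma = ph$noise_sigma %||% 0,
    masks = ph$masks %||% list(),
    seed = ph$seed %||% 1)
  list(config = config, protocol = proto)
}
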