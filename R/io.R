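# Shared table/config I/O: full-precision CSV (lossless double round trip),
# geometry YAML, ring-selection JSON sidecars, ground-truth tables and the
# provenance record every pipeline run writes next to its outputs.

#' Write a data frame as full-precision CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal mark; doubles are printed
#' with `%.17g` so they round-trip bit-exactly through [read_csv_full()].
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_full <- function(df, path) {
  fmt_col <- function(x) {
    if (is.double(x)) sprintf("%.17g", x)
    else if (is.logical(x)) as.character(x)
    else as.character(x)
  }
  cols <- lapply(df, fmt_col)
  lines <- c(
    paste(names(df), collapse = ","),
    if (nrow(df)) do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_csv_full()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_csv_full <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read detector geometry from a YAML config
#'
#' Expected keys: `energy_keV`, `distance_mm`, `pixel_pitch_mm`,
#' `beam_center` (row, col), `shape` (n_rows, n_cols), optional `bandwidth`.
#'
#' @param path YAML file path.
#' @return A [detector_geometry()].
#' @export
read_geometry_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("geometry file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("energy_keV", "distance_mm", "pixel_pitch_mm", "beam_center", "shape")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop(sprintf("geometry config missing keys: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  detector_geometry(
    energy_kev = cfg$energy_keV, distance_mm = cfg$distance_mm,
    pixel_pitch_mm = cfg$pixel_pitch_mm,
    beam_center = unlist(cfg$beam_center), shape = unlist(cfg$shape),
    bandwidth = cfg$bandwidth %||% 0
  )
}

#' Write detector geometry as YAML
#' @param geom A [detector_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry_yaml <- function(geom, path) {
  # coerce numerics explicitly so the emitted YAML is independent of whether
  # values arrived as integer or double (bit-stable provenance)
  yaml::write_yaml(list(
    energy_keV = as.numeric(geom$energy), distance_mm = as.numeric(geom$distance),
    pixel_pitch_mm = as.numeric(geom$pixel_pitch),
    beam_center = as.numeric(geom$beam_center),
    shape = as.integer(c(geom$n_rows, geom$n_cols)),
    bandwidth = as.numeric(geom$bandwidth)
  ), path)
  invisible(path)
}

#' Export a ring selection (mask TIFF + JSON sidecar)
#'
#' The mask is written as a single-page float TIFF (1 inside, 0 outside) and
#' the band parameters as `<path>.json`.
#'
#' @param ring A [ring_mask()].
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
write_ring <- function(ring, path) {
  write_map_tiff(ring$mask + 0, path)
  jsonlite::write_json(
    list(two_theta_center = ring$two_theta_center, phi_theta = ring$phi_theta,
         hkl = ring$hkl, shape = c(ring$n_rows, ring$n_cols)),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a ring selection written by [write_ring()]
#' @param path TIFF path (with `<path>.json` sidecar).
#' @return A `ring_selection`.
#' @export
read_ring <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop(sprintf("ring sidecar not found: %s", meta_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mask <- read_map_tiff(path) > 0.5
  idx <- which(mask, arr.ind = TRUE)
  structure(
    list(mask = mask, pixels = unname(idx),
         two_theta_center = meta$two_theta_center, phi_theta = meta$phi_theta,
         hkl = meta$hkl, n_rows = nrow(mask), n_cols = ncol(mask)),
    class = "ring_selection"
  )
}

#' Export simulator ground truth as CSV
#'
#' One row per crystal per time point: `crystal_id, step, time_s,
#' theta_tilt_rad, chi_rad` plus, when spot tracks exist, `frame, row_px,
#' col_px`. A JSON parameter sidecar `<path>.json` records the generating
#' parameters.
#'
#' @param truth A [simulate_orientations()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  n_t <- nrow(truth$theta)
  df <- data.frame(
    crystal_id = rep(seq_len(truth$n_crystals), each = n_t),
    step = rep(0:(n_t - 1L), truth$n_crystals),
    time_s = rep((0:(n_t - 1L)) * truth$dt, truth$n_crystals),
    theta_tilt_rad = as.vector(truth$theta),
    chi_rad = as.vector(truth$chi)
  )
  write_csv_full(df, path)
  if (!is.null(truth$spot_tracks)) {
    nf <- nrow(truth$spot_tracks$row)
    trk <- data.frame(
      crystal_id = rep(seq_len(truth$n_crystals), each = nf),
      frame = rep(seq_len(nf), truth$n_crystals),
      row_px = as.vector(truth$spot_tracks$row),
      col_px = as.vector(truth$spot_tracks$col)
    )
    write_csv_full(trk, sub("\\.csv$", "_tracks.csv", path))
  }
  jsonlite::write_json(
    list(n_crystals = truth$n_crystals, n_steps = truth$n_steps,
         d_rot_true = truth$d_rot_true, dt = truth$dt, seed = truth$seed,
         theta0_window = truth$theta0_window, radius_nm = truth$radius_nm),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write the provenance record of a run
#'
#' Machine-readable JSON (config, seed, package and R versions) written
#' alongside outputs so any run can be reproduced bit-identically.
#'
#' @param config Named list of run parameters.
#' @param seed Integer seed of the run.
#' @param out_dir Output directory.
#' @param stage Character stage name.
#' @return The provenance file path, invisibly.
#' @export
write_provenance <- function(config, seed, out_dir, stage) {
  path <- file.path(out_dir, paste0(stage, "_provenance.json"))
  jsonlite::write_json(
    list(
      stage = stage, seed = seed, config = config,
      package = "dxblink",
      package_version = as.character(utils::packageVersion("dxblink")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
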