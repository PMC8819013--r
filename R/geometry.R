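# Diffraction geometry: energy/wavelength conversion, Bragg angles, the
# pixel <-> (2theta, chi) mapping for a flat detector at normal incidence,
# ring masks and the Scherrer crystallite-size estimate.
#
# Conventions (fixed, the instruments leave them open):
#  * pixel (1,1) is the top-left pixel CENTRE; row grows downward, col rightward;
#    continuous coordinates interpolate between centres.
#  * chi is measured anticlockwise from the +col axis, range (-pi, pi].
#  * all angles are radians; 2theta = arctan(r / distance) (flat detector,
#    normal incidence -- adequate at the short working distances used here).

#: hc in keV * Angstrom
.KEV_ANGSTROM <- 12.3984

#: conventional lattice constant of fcc gold, Angstrom
AU_LATTICE_A <- 4.0782

#' Convert photon energy to wavelength
#'
#' @param energy_kev Photon energy in keV. Must be positive.
#' @return Wavelength in Angstrom (`12.3984 / energy_kev`).
#' @examples
#' wavelength_from_energy(15.8)
#' @export
wavelength_from_energy <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(!is.finite(energy_kev)) || any(energy_kev <= 0)) {
    stop("`energy_kev` must be positive and finite", call. = FALSE)
  }
  .KEV_ANGSTROM / energy_kev
}

#' Bragg scattering angle 2theta for a cubic reflection
#'
#' Computes the full scattering angle for Miller indices `hkl` of a cubic
#' lattice: d = a / sqrt(h^2 + k^2 + l^2), 2theta = 2 asin(lambda / (2 d)).
#'
#' @param wavelength Wavelength in Angstrom.
#' @param lattice_constant Cubic lattice constant in Angstrom
#'   (default: gold, `AU_LATTICE_A`).
#' @param hkl Integer Miller index triple, not all zero.
#' @return 2theta in radians.
#' @examples
#' bragg_two_theta(1.5406, hkl = c(1, 1, 1))  # Au(111) at Cu K-alpha
#' @export
bragg_two_theta <- function(wavelength, lattice_constant = AU_LATTICE_A, hkl = c(1, 1, 1)) {
  if (!is.numeric(wavelength) || wavelength <= 0) {
    stop("`wavelength` must be positive", call. = FALSE)
  }
  if (!is.numeric(lattice_constant) || lattice_constant <= 0) {
    stop("`lattice_constant` must be positive", call. = FALSE)
  }
  hkl <- as.numeric(hkl)
  if (length(hkl) != 3L || all(hkl == 0)) {
    stop("`hkl` must be a Miller index triple, not (0,0,0)", call. = FALSE)
  }
  d <- lattice_constant / sqrt(sum(hkl^2))
  s <- wavelength / (2 * d)
  if (s > 1) {
    stop(sprintf(
      "reflection (%d,%d,%d) unreachable: lambda/(2d) = %.4f > 1",
      hkl[1], hkl[2], hkl[3], s
    ), call. = FALSE)
  }
  2 * asin(s)
}

#' Detector geometry
#'
#' Bundles the parameters needed to map detector pixels to scattering angles:
#' beam energy, sample-to-detector distance (normal incidence), pixel pitch,
#' beam centre and detector shape. The wavelength is derived and cached.
#'
#' @param energy_kev Beam (peak) energy in keV.
#' @param distance_mm Sample-to-detector distance in mm.
#' @param pixel_pitch_mm Pixel pitch in mm/pixel (square pixels).
#' @param beam_center Numeric length-2 `(row, col)` of the direct-beam
#'   position in continuous pixel coordinates.
#' @param shape Integer length-2 `(n_rows, n_cols)`.
#' @param bandwidth Fractional energy bandwidth dE/E (0 for a monochromatic
#'   source; ~0.1 for the pink beam used for spot tracking).
#' @return An object of class `detector_geometry`.
#' @examples
#' detector_geometry(15.8, 50, 0.1, c(256, 256), c(512, 512), bandwidth = 0.1)
#' @export
detector_geometry <- function(energy_kev, distance_mm, pixel_pitch_mm,
                              beam_center, shape, bandwidth = 0) {
  if (distance_mm <= 0) stop("`distance_mm` must be positive", call. = FALSE)
  if (pixel_pitch_mm <= 0) stop("`pixel_pitch_mm` must be positive", call. = FALSE)
  if (bandwidth < 0) stop("`bandwidth` must be >= 0", call. = FALSE)
  if (length(beam_center) != 2L || !is.numeric(beam_center)) {
    stop("`beam_center` must be numeric (row, col)", call. = FALSE)
  }
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) {
    stop("`shape` must be positive (n_rows, n_cols)", call. = FALSE)
  }
  structure(
    list(
      energy = energy_kev,
      wavelength = wavelength_from_energy(energy_kev),
      distance = distance_mm,
      pixel_pitch = pixel_pitch_mm,
      beam_center = as.numeric(beam_center),
      n_rows = shape[1], n_cols = shape[2],
      bandwidth = bandwidth
    ),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("<detector_geometry>\n")
  cat(sprintf("  energy     : %.4f keV (lambda = %.5f A)\n", x$energy, x$wavelength))
  cat(sprintf("  distance   : %g mm, pitch %g mm/px\n", x$distance, x$pixel_pitch))
  cat(sprintf(
    "  detector   : %d x %d px, beam centre (%.2f, %.2f)\n",
    x$n_rows, x$n_cols, x$beam_center[1], x$beam_center[2]
  ))
  cat(sprintf("  bandwidth  : %g\n", x$bandwidth))
  invisible(x)
}

#' Map detector pixels to scattering angles
#'
#' @param pixel Numeric `(row, col)` pair or an n x 2 matrix of continuous
#'   pixel coordinates.
#' @param geom A [detector_geometry()].
#' @return An n x 2 matrix with columns `two_theta` and `chi` (radians); for
#'   a single pixel a named length-2 vector. `chi` lies in (-pi, pi]; the
#'   beam-centre pixel maps to `(0, 0)` by convention.
#' @export
pixel_to_angles <- function(pixel, geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  p <- if (is.matrix(pixel)) pixel else matrix(as.numeric(pixel), ncol = 2L)
  drow <- p[, 1] - geom$beam_center[1]
  dcol <- p[, 2] - geom$beam_center[2]
  r_mm <- geom$pixel_pitch * sqrt(drow^2 + dcol^2)
  two_theta <- atan(r_mm / geom$distance)
  chi <- atan2(drow, dcol)
  chi[r_mm == 0] <- 0
  chi[chi <= -pi] <- pi  # enforce (-pi, pi]
  out <- cbind(two_theta = two_theta, chi = chi)
  if (!is.matrix(pixel)) out[1, ] else out
}

#' Map scattering angles to detector pixels
#'
#' Inverse of [pixel_to_angles()] for the flat-detector model:
#' `r = distance * tan(2theta) / pixel_pitch`, `row = center_row + r sin(chi)`,
#' `col = center_col + r cos(chi)`.
#'
#' @param two_theta Scattering angle(s), radians, in `[0, pi/2)`.
#' @param chi Azimuth(s), radians.
#' @param geom A [detector_geometry()].
#' @return n x 2 matrix (columns `row`, `col`), or a length-2 vector for
#'   scalar input.
#' @export
angles_to_pixel <- function(two_theta, chi, geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  if (any(two_theta < 0) || any(two_theta >= pi / 2)) {
    stop("`two_theta` out of the flat-detector range [0, pi/2)", call. = FALSE)
  }
  r_px <- geom$distance * tan(two_theta) / geom$pixel_pitch
  out <- cbind(
    row = geom$beam_center[1] + r_px * sin(chi),
    col = geom$beam_center[2] + r_px * cos(chi)
  )
  if (length(two_theta) == 1L && length(chi) == 1L) out[1, ] else out
}

#' Per-pixel scattering-angle map
#'
#' 2theta of every pixel centre, as an `n_rows x n_cols` matrix.
#' @param geom A [detector_geometry()].
#' @return Matrix of 2theta values (radians).
#' @export
two_theta_map <- function(geom) {
  px <- cbind(
    rep(seq_len(geom$n_rows), times = geom$n_cols),
    rep(seq_len(geom$n_cols), each = geom$n_rows)
  )
  matrix(pixel_to_angles(px, geom)[, "two_theta"], geom$n_rows, geom$n_cols)
}

#' Select a powder-ring band of pixels
#'
#' Masks all pixels whose centre 2theta lies in the closed band
#' `[two_theta_center - phi_theta/2, two_theta_center + phi_theta/2]`.
#' `phi_theta` is the FULL angular width of the ring in 2theta; it is stored
#' for the downstream conversion of autocorrelation decay constants to
#' rotational diffusion coefficients.
#'
#' @param geom A [detector_geometry()].
#' @param two_theta_center Ring centre, radians.
#' @param phi_theta Full width of the band, radians (> 0).
#' @param hkl Optional Miller index triple recorded as metadata.
#' @return An object of class `ring_selection`: logical `mask` matrix,
#'   integer index matrix `pixels` (row, col), plus the band parameters.
#' @export
ring_mask <- function(geom, two_theta_center, phi_theta, hkl = NULL) {
  if (phi_theta <= 0) stop("`phi_theta` must be positive", call. = FALSE)
  tt <- two_theta_map(geom)
  lo <- two_theta_center - phi_theta / 2
  hi <- two_theta_center + phi_theta / 2
  mask <- tt >= lo & tt <= hi
  if (!any(mask)) {
    stop(sprintf(
      "ring band [%.4f, %.4f] rad selects no pixels on this detector",
      lo, hi
    ), call. = FALSE)
  }
  idx <- which(mask, arr.ind = TRUE)
  structure(
    list(
      mask = mask,
      pixels = unname(idx),
      two_theta_center = two_theta_center,
      phi_theta = phi_theta,
      hkl = hkl,
      n_rows = geom$n_rows, n_cols = geom$n_cols
    ),
    class = "ring_selection"
  )
}

#' @export
print.ring_selection <- function(x, ...) {
  cat("<ring_selection>\n")
  cat(sprintf(
    "  band  : 2theta = %.4f +/- %.4f/2 rad (phi_theta full width)\n",
    x$two_theta_center, x$phi_theta
  ))
  if (!is.null(x$hkl)) cat(sprintf("  hkl   : (%s)\n", paste(x$hkl, collapse = ",")))
  cat(sprintf("  pixels: %d of %d x %d\n", nrow(x$pixels), x$n_rows, x$n_cols))
  invisible(x)
}

#' Scherrer crystallite size
#'
#' `size = K * lambda / (beta * cos(theta))` with `beta` the peak FWHM in
#' radians and `theta` the Bragg half-angle.
#'
#' @param beta Peak full width at half maximum, radians (> 0).
#' @param theta Bragg half-angle, radians, in (0, pi/2) (0 allowed for the
#'   forward limit).
#' @param wavelength Wavelength, Angstrom.
#' @param shape_factor Dimensionless shape factor K (default 0.9).
#' @return Crystallite size in Angstrom.
#' @export
scherrer_size <- function(beta, theta, wavelength, shape_factor = 0.9) {
  if (any(beta <= 0)) stop("`beta` must be positive", call. = FALSE)
  if (any(theta < 0) || any(theta >= pi / 2)) {
    stop("`theta` must lie in [0, pi/2)", call. = FALSE)
  }
  shape_factor * wavelength / (beta * cos(theta))
}
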