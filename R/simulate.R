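# Synthetic diffraction-movie generator.
#
# Nanocrystal orientations follow small-angle 2-D rotational Brownian motion:
# the tilt of the diffracting plane normal away from the exact Bragg
# orientation (theta_tilt) and the azimuth of the diffracted beam (chi) each
# receive independent Gaussian increments of variance 2 * d_rot * dt per step.
# A Gaussian rocking curve converts tilt to diffracted intensity; a crystal's
# spot sits at detector angles (2theta_ref + 2 * theta_tilt, chi) -- tilting a
# crystal by delta swings the reflected beam by 2 * delta.

# run `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Beam model for the simulator
#'
#' A monochromatic beam blinks: intensity follows a Gaussian rocking curve of
#' width `rocking_width` in tilt. A broadband ("pink") beam keeps spots lit
#' over a much wider tilt range; its effective width adds, in quadrature, the
#' bandwidth term `tan(theta_B) * bandwidth` obtained by differentiating the
#' Bragg law.
#'
#' @param mode `"monochromatic"` or `"broadband"`.
#' @param rocking_width Gaussian sigma of the reflectivity curve vs tilt,
#'   radians (> 0). Default 1 mrad.
#' @param bandwidth Fractional energy bandwidth dE/E; required > 0 for
#'   broadband mode.
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(mode = c("monochromatic", "broadband"),
                       rocking_width = 1e-3, bandwidth = 0) {
  mode <- match.arg(mode)
  if (rocking_width <= 0) stop("`rocking_width` must be positive", call. = FALSE)
  if (mode == "broadband" && bandwidth <= 0) {
    stop("broadband mode requires `bandwidth` > 0", call. = FALSE)
  }
  structure(list(mode = mode, rocking_width = rocking_width, bandwidth = bandwidth),
            class = "beam_model")
}

#' Relative diffracted intensity vs crystal tilt
#'
#' @param theta_tilt Tilt(s) away from the exact Bragg orientation, radians.
#' @param beam A [beam_model()].
#' @param theta_bragg Bragg half-angle of the reflection, radians; required
#'   for broadband mode (sets the bandwidth contribution to the effective
#'   width).
#' @return Relative intensity in `[0, 1]`; 1 at exact Bragg condition.
#' @export
rocking_intensity <- function(theta_tilt, beam, theta_bragg = NULL) {
  stopifnot(inherits(beam, "beam_model"))
  w <- effective_rocking_width(beam, theta_bragg)
  exp(-theta_tilt^2 / (2 * w^2))
}

effective_rocking_width <- function(beam, theta_bragg = NULL) {
  if (beam$mode == "monochromatic") return(beam$rocking_width)
  if (is.null(theta_bragg)) {
    stop("broadband mode needs `theta_bragg` to derive the bandwidth width", call. = FALSE)
  }
  sqrt(beam$rocking_width^2 + (tan(theta_bragg) * beam$bandwidth)^2)
}

#' Simulate rotational Brownian orientation paths
#'
#' Each of `n_crystals` crystals gets an initial tilt drawn uniformly from
#' `[-theta0_window, theta0_window]` and an initial azimuth uniform on
#' (-pi, pi]; both coordinates then perform independent Brownian motion with
#' increment variance `2 * d_rot * dt` per step (small-angle 2-D approximation
#' of rotational diffusion).
#'
#' @param n_crystals Number of crystals.
#' @param d_rot Rotational diffusion coefficient, rad^2/s (>= 0).
#' @param dt Time step, s (> 0).
#' @param n_steps Number of steps; paths have `n_steps + 1` states.
#' @param seed Integer seed (mandatory; same seed and parameters give
#'   bit-identical output).
#' @param theta0_window Half-width of the initial tilt capture window,
#'   radians.
#' @param chi0 Optional vector of initial azimuths (length `n_crystals`,
#'   radians); default: drawn uniformly on (-pi, pi]. Fixing them (e.g.
#'   evenly spaced) gives well-separated spots for tracking studies.
#' @param radius_nm Nominal crystal radius (metadata only; the epitaxial gold
#'   crystals used in vivo are ~60-80 nm across, so default radius 35 nm).
#' @return An object of class `ground_truth` with `(n_steps+1) x n_crystals`
#'   matrices `theta` (tilt) and `chi`, plus the generating parameters.
#' @export
simulate_orientations <- function(n_crystals, d_rot, dt, n_steps, seed,
                                  theta0_window = 2e-3, radius_nm = 35,
                                  chi0 = NULL) {
  if (d_rot < 0) stop("`d_rot` must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (radius_nm <= 0) stop("`radius_nm` must be positive", call. = FALSE)
  n_crystals <- as.integer(n_crystals)
  n_steps <- as.integer(n_steps)
  sd_step <- sqrt(2 * d_rot * dt)
  if (!is.null(chi0) && length(chi0) != n_crystals) {
    stop("`chi0` must have one azimuth per crystal", call. = FALSE)
  }
  paths <- with_seed(seed, {
    theta0 <- runif(n_crystals, -theta0_window, theta0_window)
    if (is.null(chi0)) chi0 <- runif(n_crystals, -pi, pi)
    chi0[chi0 <= -pi] <- pi
    dtheta <- matrix(rnorm(n_steps * n_crystals, sd = sd_step), n_steps, n_crystals)
    dchi <- matrix(rnorm(n_steps * n_crystals, sd = sd_step), n_steps, n_crystals)
    list(
      theta = rbind(theta0, apply_cumsum(theta0, dtheta)),
      chi = rbind(chi0, apply_cumsum(chi0, dchi))
    )
  })
  dimnames(paths$theta) <- NULL
  dimnames(paths$chi) <- NULL
  structure(
    list(
      theta = paths$theta, chi = paths$chi,
      n_crystals = n_crystals, n_steps = n_steps,
      d_rot_true = d_rot, dt = dt, seed = seed,
      theta0_window = theta0_window, radius_nm = radius_nm,
      spot_tracks = NULL
    ),
    class = "ground_truth"
  )
}

# cumulative sum of increments on top of an initial state; d_rot = 0 gives
# exactly constant paths (no floating error accumulates: increments are 0)
apply_cumsum <- function(x0, inc) {
  if (nrow(inc) == 0L) return(inc)
  sweep(apply(inc, 2, cumsum), 2, x0, "+")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf(
    "  %d crystals, %d steps of %g s (d_rot = %g rad^2/s, seed %d)\n",
    x$n_crystals, x$n_steps, x$dt, x$d_rot_true, x$seed
  ))
  if (!is.null(x$spot_tracks)) {
    cat(sprintf("  spot tracks: %d frames\n", nrow(x$spot_tracks$row)))
  }
  invisible(x)
}

#' Rotational diffusion coefficient from the Stokes-Einstein-Debye relation
#'
#' Advisory helper to pick a physically plausible `d_rot` for a colloidal
#' sphere: `D_R = k_B T / (8 pi eta r^3)`. Not used by any analysis.
#'
#' @param temperature_K Absolute temperature, K.
#' @param viscosity_Pa_s Dynamic viscosity, Pa s (water at 25 C: 8.9e-4).
#' @param radius_nm Sphere radius, nm.
#' @return Rotational diffusion coefficient, rad^2/s.
#' @export
stokes_einstein_debye <- function(temperature_K, viscosity_Pa_s, radius_nm) {
  kb <- 1.380649e-23
  r <- radius_nm * 1e-9
  kb * temperature_K / (8 * pi * viscosity_Pa_s * r^3)
}

# Shared renderer. Deposits, for every exposure sub-step, photon counts
# amplitude = photons_per_crystal * rocking_intensity / substeps at
# angles_to_pixel(two_theta_ref + 2 * theta_tilt, chi) through a truncated
# Gaussian point-spread footprint (normalised to unit sum before edge
# clipping; photons falling off the detector are counted in `lost`).
render_movie <- function(truth, geom, beam, two_theta_ref, theta_bragg,
                         photons_per_crystal, background, exposure,
                         poisson, seed, psf_sigma = 1, psf_radius = 3,
                         track_spots = FALSE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(geom, "detector_geometry"))
  if (exposure <= 0) stop("`exposure` must be positive", call. = FALSE)
  substeps <- exposure / truth$dt
  if (abs(substeps - round(substeps)) > 1e-9) {
    stop("`exposure` must be an integer multiple of the ground-truth `dt`", call. = FALSE)
  }
  substeps <- as.integer(round(substeps))
  n_frames <- truth$n_steps %/% substeps
  if (n_frames < 1L) stop("ground truth too short for one exposure", call. = FALSE)
  nr <- geom$n_rows; nc <- geom$n_cols; npx <- nr * nc
  nct <- truth$n_crystals

  # PSF stencil offsets (integer), weights evaluated per sub-pixel position
  off <- expand.grid(dr = -psf_radius:psf_radius, dc = -psf_radius:psf_radius)
  off <- off[off$dr^2 + off$dc^2 <= psf_radius^2 + 1e-9, ]
  k_off <- nrow(off)

  counts <- array(0, dim = c(nr, nc, n_frames))
  lost <- 0
  if (track_spots) {
    trk_row <- matrix(NA_real_, n_frames, nct)
    trk_col <- matrix(NA_real_, n_frames, nct)
  }

  for (f in seq_len(n_frames)) {
    # sub-step states within this exposure (state after each step)
    idx <- ((f - 1L) * substeps + 1L):(f * substeps) + 1L
    th <- truth$theta[idx, , drop = FALSE]          # substeps x nct
    ch <- truth$chi[idx, , drop = FALSE]
    amp <- photons_per_crystal *
      rocking_intensity(th, beam, theta_bragg) / substeps
    tt <- two_theta_ref + 2 * th
    # a tilt past the exact axis flips the diffracted beam to the opposite
    # azimuth: continue smoothly through 2theta = 0
    flip <- tt < 0
    tt <- abs(tt)
    visible <- tt < pi / 2
    r_px <- geom$distance * tan(pmin(tt, pi / 2 - 1e-9)) / geom$pixel_pitch
    chf <- ch + ifelse(flip, pi, 0)
    row0 <- geom$beam_center[1] + r_px * sin(chf)
    col0 <- geom$beam_center[2] + r_px * cos(chf)
    amp <- amp * visible
    keep <- amp > 0
    a <- amp[keep]; r0 <- row0[keep]; c0 <- col0[keep]
    if (track_spots) {
      # amplitude-weighted sub-step mean position = rendered spot centroid
      wsum <- colSums(matrix(amp, nrow(th), nct))
      wr <- colSums(matrix(amp * row0, nrow(th), nct))
      wc <- colSums(matrix(amp * col0, nrow(th), nct))
      ok <- wsum > 0
      trk_row[f, ok] <- wr[ok] / wsum[ok]
      trk_col[f, ok] <- wc[ok] / wsum[ok]
    }
    if (length(a)) {
      ri <- round(r0); ci <- round(c0)
      # stamp rows: length(a) x k_off, row-centre offsets relative to (ri, ci)
      rp <- outer(ri, off$dr, "+")
      cp <- outer(ci, off$dc, "+")
      w <- exp(-((rp - r0)^2 + (cp - c0)^2) / (2 * psf_sigma^2))
      w <- w / rowSums(w) * a
      inb <- rp >= 1 & rp <= nr & cp >= 1 & cp <= nc
      lost <- lost + sum(w[!inb])
      lin <- (cp[inb] - 1) * nr + rp[inb]
      acc <- rowsum(w[inb], lin, reorder = FALSE)
      fr <- numeric(npx)
      fr[as.integer(rownames(acc))] <- acc[, 1]
      counts[, , f] <- fr
    }
    counts[, , f] <- counts[, , f] + background
  }

  if (poisson) {
    if (is.null(seed)) stop("`seed` is required when `poisson = TRUE`", call. = FALSE)
    counts <- with_seed(seed, array(rpois(length(counts), counts), dim = dim(counts)))
  }
  movie <- diffraction_movie(counts, exposure = exposure)
  attr(movie, "photons_lost") <- lost
  if (track_spots) {
    truth$spot_tracks <- list(row = trk_row, col = trk_col)
    list(movie = movie, truth = truth)
  } else {
    movie
  }
}

#' Render a DXB blinking movie (monochromatic beam)
#'
#' Each crystal deposits `photons_per_crystal * rocking_intensity(tilt)`
#' counts per frame (averaged over the orientation sub-steps within each
#' exposure) at the detector position of its diffracted beam, through a
#' truncated-Gaussian point-spread footprint. A uniform background is added
#' and the movie can be Poisson-resampled pixel-wise.
#'
#' @param truth A [simulate_orientations()] result. Its `dt` must divide the
#'   exposure; `exposure / dt` orientation sub-steps are averaged per frame.
#' @param geom A [detector_geometry()].
#' @param ring A [ring_mask()]; its `two_theta_center` anchors the spots'
#'   reference scattering angle.
#' @param beam A monochromatic [beam_model()].
#' @param photons_per_crystal Peak photons per crystal per frame.
#' @param background Uniform background, counts/pixel/frame.
#' @param exposure Exposure time per frame, s (default 0.2).
#' @param poisson Poisson-resample every pixel?
#' @param seed Seed for the Poisson noise (required if `poisson`).
#' @param psf_sigma,psf_radius Point-spread Gaussian sigma and truncation
#'   radius, pixels.
#' @return A [diffraction_movie()] (attribute `photons_lost` counts photons
#'   clipped at the detector edge).
#' @export
render_dxb_movie <- function(truth, geom, ring, beam, photons_per_crystal,
                             background = 0, exposure = 0.2, poisson = FALSE,
                             seed = NULL, psf_sigma = 1, psf_radius = 3) {
  stopifnot(inherits(ring, "ring_selection"))
  if (beam$mode != "monochromatic") {
    stop("DXB rendering requires a monochromatic beam", call. = FALSE)
  }
  if (ring$n_rows != geom$n_rows || ring$n_cols != geom$n_cols) {
    stop("ring selection and detector geometry shapes differ", call. = FALSE)
  }
  render_movie(truth, geom, beam,
    two_theta_ref = ring$two_theta_center,
    theta_bragg = ring$two_theta_center / 2,
    photons_per_crystal = photons_per_crystal, background = background,
    exposure = exposure, poisson = poisson, seed = seed,
    psf_sigma = psf_sigma, psf_radius = psf_radius, track_spots = FALSE
  )
}

#' Render a DXT spot-tracking movie (broadband beam)
#'
#' With a broadband beam the effective rocking curve is wide, so spots stay
#' lit while they move across the detector following each crystal's
#' (tilt, azimuth) path. The returned ground truth gains `spot_tracks`: the
#' exact amplitude-weighted sub-pixel spot centre per frame and crystal.
#'
#' @inheritParams render_dxb_movie
#' @param two_theta_ref Reference scattering angle of the tracked reflection,
#'   radians.
#' @param exposure Exposure time per frame, s (default 0.01 = 10 ms).
#' @return `list(movie = diffraction_movie, truth = ground_truth)` with
#'   `truth$spot_tracks` filled in.
#' @export
render_dxt_movie <- function(truth, geom, beam, two_theta_ref,
                             photons_per_crystal, background = 0,
                             exposure = 0.01, poisson = FALSE, seed = NULL,
                             psf_sigma = 1, psf_radius = 3) {
  if (beam$mode != "broadband") {
    stop("DXT rendering requires a broadband beam", call. = FALSE)
  }
  render_movie(truth, geom, beam,
    two_theta_ref = two_theta_ref, theta_bragg = two_theta_ref / 2,
    photons_per_crystal = photons_per_crystal, background = background,
    exposure = exposure, poisson = poisson, seed = seed,
    psf_sigma = psf_sigma, psf_radius = psf_radius, track_spots = TRUE
  )
}

#' Poisson-resample a noiseless movie
#'
#' Draws every pixel of every frame from a Poisson distribution whose mean is
#' the stored (noiseless) count. Lets one noiseless render serve as the mean
#' field for matched noisy/noiseless comparisons.
#'
#' @param movie A [diffraction_movie()].
#' @param seed Integer seed.
#' @return A [diffraction_movie()] of integer counts.
#' @export
poisson_sample_movie <- function(movie, seed) {
  stopifnot(inherits(movie, "diffraction_movie"))
  counts <- with_seed(seed, array(
    rpois(length(movie$counts), movie$counts),
    dim = dim(movie$counts)
  ))
  diffraction_movie(counts, exposure = movie$exposure)
}
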