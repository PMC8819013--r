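# Shared fixture builders. All fixtures are generated in code at test time.
#
# The DXB recovery world is deliberately scaled: the d_rot grid used in the
# recovery tests (0.01-0.16 rad^2/s) is orders of magnitude faster than the
# physical regime, so every angular scale on the detector (rocking width,
# pixel, point-spread, ring radius) is scaled up with it such that the
# blinking decorrelation stays between the frame interval and a tenth of the
# trace length across the whole grid (see the methods vignette).

# coarse-angular-pixel DXB world: 16 x 16 detector, ~0.77 rad/px, Au(111)
# ring at ~1 px radius, rocking sigma 0.42 rad
dxb_world <- function() {
  geom <- detector_geometry(
    energy_kev = 8.0478, distance_mm = 1, pixel_pitch_mm = 0.77,
    beam_center = c(8.5, 8.5), shape = c(16, 16)
  )
  tt <- bragg_two_theta(geom$wavelength, hkl = c(1, 1, 1))
  list(
    geom = geom,
    ring = ring_mask(geom, tt, phi_theta = 0.9, hkl = c(1, 1, 1)),
    beam = beam_model("monochromatic", rocking_width = 0.42)
  )
}

# render one DXB movie of the scaled world (500 frames at 0.2 s, 200
# crystals, wide stationary capture window)
dxb_movie <- function(d_rot, seed, n_frames = 500, n_crystals = 200,
                      photons = 2000, world = dxb_world()) {
  substeps <- 10L
  truth <- simulate_orientations(
    n_crystals, d_rot, dt = 0.2 / substeps, n_steps = n_frames * substeps,
    seed = seed, theta0_window = 6
  )
  movie <- render_dxb_movie(
    truth, world$geom, world$ring, world$beam,
    photons_per_crystal = photons, background = 0.5, exposure = 0.2,
    psf_sigma = 0.43, psf_radius = 2
  )
  list(movie = movie, truth = truth, world = world)
}

# broadband DXT world: conventional geometry (50 mm, 0.1 mm pixels),
# 20 spots on a 2theta = 0.1 rad ring, 10 ms frames
dxt_world <- function() {
  list(
    geom = detector_geometry(
      energy_kev = 15.8, distance_mm = 50, pixel_pitch_mm = 0.1,
      beam_center = c(100.5, 100.5), shape = c(200, 200), bandwidth = 0.1
    ),
    beam = beam_model("broadband", rocking_width = 0.04, bandwidth = 0.1),
    two_theta_ref = 0.10
  )
}

dxt_movie <- function(d_rot = 5e-6, seed = 42, n_frames = 1000, n_spots = 20,
                      world = dxt_world()) {
  truth <- simulate_orientations(
    n_spots, d_rot, dt = 0.01, n_steps = n_frames, seed = seed,
    theta0_window = 0.005,
    chi0 = seq(-pi + 0.1, pi - 0.2, length.out = n_spots)
  )
  res <- render_dxt_movie(
    truth, world$geom, world$beam, two_theta_ref = world$two_theta_ref,
    photons_per_crystal = 5000, background = 0, exposure = 0.01
  )
  c(res, list(world = world))
}

# exact ACF curve from known parameters
model_acf_curve <- function(A, gamma, y, lags) {
  structure(
    list(lags = lags, values = A * exp(-gamma * lags) + y,
         n_frames_used = 4L * length(lags)),
    class = "acf_curve"
  )
}

# brute-force ACF oracle: double loop, full-trace mean in the denominator
acf_oracle <- function(trace, max_lag) {
  n <- length(trace)
  m <- mean(trace)
  vapply(seq_len(max_lag), function(k) {
    s <- 0
    for (t in 1:(n - k)) s <- s + trace[t] * trace[t + k]
    (s / (n - k)) / m^2
  }, numeric(1))
}

# match recovered trajectories to simulator spot tracks; returns per-track
# maximum position error and the matched crystal ids
match_tracks <- function(traj, truth) {
  ids <- unique(traj$trajectory_id)
  err <- numeric(length(ids))
  crystal <- integer(length(ids))
  for (j in seq_along(ids)) {
    w <- traj[traj$trajectory_id == ids[j], ]
    tr_r <- truth$spot_tracks$row[w$frame, , drop = FALSE]
    tr_c <- truth$spot_tracks$col[w$frame, , drop = FALSE]
    k <- which.min((tr_r[1, ] - w$row[1])^2 + (tr_c[1, ] - w$col[1])^2)
    crystal[j] <- k
    err[j] <- max(sqrt((tr_r[, k] - w$row)^2 + (tr_c[, k] - w$col)^2))
  }
  list(max_err = err, crystal = crystal)
}
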