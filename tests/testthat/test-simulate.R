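test_that("orientation paths obey the Brownian variance law", {
  # frozen dynamics
  gt0 <- simulate_orientations(50, 0, dt = 0.1, n_steps = 30, seed = 1)
  expect_true(all(gt0$theta == matrix(gt0$theta[1, ], 31, 50, byrow = TRUE)))
  expect_true(all(gt0$chi == matrix(gt0$chi[1, ], 31, 50, byrow = TRUE)))
  # Var(theta(t) - theta(0)) = 2 d t within 5% at n = 10,000
  d <- 0.05
  gt <- simulate_orientations(10000, d, dt = 0.01, n_steps = 100, seed = 42,
                              theta0_window = 0.01)
  v_theta <- var(gt$theta[101, ] - gt$theta[1, ])
  v_chi <- var(gt$chi[101, ] - gt$chi[1, ])
  expect_equal(v_theta, 2 * d * 1, tolerance = 0.05)
  expect_equal(v_chi, 2 * d * 1, tolerance = 0.05)
  expect_error(simulate_orientations(5, -1, 0.1, 10, 1), ">= 0")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_orientations(20, 0.02, 0.01, 50, seed = 7)
  b <- simulate_orientations(20, 0.02, 0.01, 50, seed = 7)
  expect_identical(a, b)
  c_ <- simulate_orientations(20, 0.02, 0.01, 50, seed = 8)
  expect_false(identical(a$theta, c_$theta))
  # explicit chi0 is honoured
  chi0 <- seq(-3, 3, length.out = 20)
  d <- simulate_orientations(20, 0.02, 0.01, 50, seed = 7, chi0 = chi0)
  expect_equal(d$chi[1, ], chi0)
})

test_that("rocking curve evaluates the Gaussian reflectivity", {
  mono <- beam_model("monochromatic", rocking_width = 2e-3)
  expect_equal(rocking_intensity(0, mono), 1.0)
  expect_equal(rocking_intensity(2e-3, mono), exp(-0.5), tolerance = 1e-12)
  bb <- beam_model("broadband", rocking_width = 2e-3, bandwidth = 0.1)
  expect_gt(effective_rocking_width <- dxblink:::effective_rocking_width(bb, 0.17),
            2e-3)
  # broadband keeps the spot lit where the monochromatic beam is dark
  expect_gt(rocking_intensity(6e-3, bb, theta_bragg = 0.17),
            rocking_intensity(6e-3, mono))
  expect_error(beam_model("broadband", bandwidth = 0), "bandwidth")
  expect_error(beam_model("monochromatic", rocking_width = 0), "positive")
})

test_that("DXB rendering conserves photons with noise disabled", {
  world <- dxb_world()
  # interior spots: tiny d_rot and capture window keep everything on-detector
  truth <- simulate_orientations(30, 1e-4, dt = 0.02, n_steps = 200, seed = 3,
                                 theta0_window = 0.05)
  movie <- render_dxb_movie(truth, world$geom, world$ring, world$beam,
                            photons_per_crystal = 100, background = 0.25,
                            exposure = 0.2, psf_sigma = 0.43, psf_radius = 2)
  expect_identical(attr(movie, "photons_lost"), 0)
  # oracle: per frame, photons * mean sub-step rocking intensity + background
  th <- truth$theta[-1, , drop = FALSE]
  inten <- rocking_intensity(th, world$beam)
  frame_idx <- rep(1:20, each = 10)
  expected <- sum(100 * rowsum(inten, frame_idx) / 10) +
    20 * 0.25 * prod(dim(movie$counts)[1:2])
  expect_equal(sum(movie$counts), expected, tolerance = 1e-9)
  # static scene: every frame identical
  truth0 <- simulate_orientations(10, 0, dt = 0.02, n_steps = 100, seed = 4,
                                  theta0_window = 0.05)
  m0 <- render_dxb_movie(truth0, world$geom, world$ring, world$beam,
                         photons_per_crystal = 100, exposure = 0.2)
  for (f in 2:10) expect_equal(m0$counts[, , f], m0$counts[, , 1])
})

test_that("Poisson resampling preserves the mean field", {
  world <- dxb_world()
  truth <- simulate_orientations(50, 0.01, dt = 0.02, n_steps = 600, seed = 5,
                                 theta0_window = 1)
  clean <- render_dxb_movie(truth, world$geom, world$ring, world$beam,
                            photons_per_crystal = 500, background = 2,
                            exposure = 0.2, psf_sigma = 0.43, psf_radius = 2)
  noisy <- poisson_sample_movie(clean, seed = 6)
  expect_true(all(noisy$counts == round(noisy$counts)))
  # per-pixel temporal mean within 3 standard errors of the noiseless mean
  nf <- dim(clean$counts)[3]
  mean_clean <- apply(clean$counts, c(1, 2), mean)
  mean_noisy <- apply(noisy$counts, c(1, 2), mean)
  se <- sqrt(mean_clean / nf)
  frac_in <- mean(abs(mean_noisy - mean_clean) <= 3 * se)
  expect_gt(frac_in, 0.99)
  # determinism of the resampling
  expect_identical(noisy, poisson_sample_movie(clean, seed = 6))
})

test_that("DXT spot tracks equal the rendered spot centroids", {
  sim <- dxt_movie(d_rot = 5e-6, seed = 9, n_frames = 40)
  truth <- sim$truth
  expect_equal(dim(truth$spot_tracks$row), c(40L, 20L))
  # all tracks present and constant-d sanity: detect each frame's spots and
  # compare centroids with the recorded tracks
  spots <- detect_spots_movie(sim$movie, threshold = 50, min_separation = 5)
  for (f in c(1, 20, 40)) {
    sf <- spots[spots$frame == f, ]
    expect_identical(nrow(sf), 20L)
    for (k in 1:20) {
      dd <- sqrt((sf$row - truth$spot_tracks$row[f, k])^2 +
                 (sf$col - truth$spot_tracks$col[f, k])^2)
      expect_lt(min(dd), 0.1)
    }
  }
  # d_rot = 0 gives constant tracks
  w <- dxt_world()
  t0 <- simulate_orientations(5, 0, 0.01, 30, seed = 10, theta0_window = 0.004,
                              chi0 = seq(-2, 2, length.out = 5))
  r0 <- render_dxt_movie(t0, w$geom, w$beam, two_theta_ref = w$two_theta_ref,
                         photons_per_crystal = 1000, exposure = 0.01)
  expect_equal(apply(r0$truth$spot_tracks$row, 2, sd), rep(0, 5))
  expect_equal(apply(r0$truth$spot_tracks$col, 2, sd), rep(0, 5))
})

test_that("doubling d_rot doubles the mean squared angular step", {
  s1 <- simulate_orientations(10, 0.005, 0.01, 10000, seed = 11)
  s2 <- simulate_orientations(10, 0.010, 0.01, 10000, seed = 12)
  ms1 <- mean(diff(s1$theta)^2)
  ms2 <- mean(diff(s2$theta)^2)
  expect_equal(ms2 / ms1, 2, tolerance = 0.1)
})

test_that("Stokes-Einstein-Debye helper gives the textbook value", {
  # water at 298 K, eta = 8.9e-4 Pa s, r = 35 nm
  d <- stokes_einstein_debye(298, 8.9e-4, 35)
  expect_equal(d, 1.380649e-23 * 298 / (8 * pi * 8.9e-4 * (35e-9)^3),
               tolerance = 1e-12)
  expect_equal(d, 4290, tolerance = 0.001)  # rad^2/s, hand-checked magnitude
})
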