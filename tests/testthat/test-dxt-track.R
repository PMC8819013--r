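render_gauss_spot <- function(shape, row, col, amp = 500, sigma = 1) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  amp * exp(-((r - row)^2 + (cc - col)^2) / (2 * sigma^2))
}

test_that("detect_spots finds sub-pixel centroids and merges close maxima", {
  expect_identical(nrow(detect_spots(matrix(0, 32, 32), threshold = 1)), 0L)
  # single spot at a known sub-pixel position
  fr <- render_gauss_spot(c(64, 64), 20.3, 31.7)
  s <- detect_spots(fr, threshold = 5, background = 0)
  expect_identical(nrow(s), 1L)
  expect_lt(abs(s$row - 20.3), 0.05)
  expect_lt(abs(s$col - 31.7), 0.05)
  # two separated spots -> two detections; closer than min_separation -> one
  fr2 <- render_gauss_spot(c(64, 64), 15, 15) +
    render_gauss_spot(c(64, 64), 40.5, 41.5, amp = 300)
  s2 <- detect_spots(fr2, threshold = 5, min_separation = 5, background = 0)
  expect_identical(nrow(s2), 2L)
  fr3 <- render_gauss_spot(c(64, 64), 30, 30) +
    render_gauss_spot(c(64, 64), 30, 33, amp = 300)
  s3 <- detect_spots(fr3, threshold = 5, min_separation = 6, background = 0)
  expect_identical(nrow(s3), 1L)
})

test_that("link_trajectories follows, splits and bridges tracks", {
  # single static spot
  still <- data.frame(frame = 1:100, row = 10, col = 12, intensity = 1)
  tr <- link_trajectories(still, max_disp = 3)
  expect_identical(length(unique(tr$trajectory_id)), 1L)
  expect_identical(trajectory_durations(tr)$n_points, 100L)
  # two spots drifting in opposite directions keep their identities
  fr <- rep(1:50, each = 2)
  drift <- data.frame(
    frame = fr,
    row = ifelse(seq_along(fr) %% 2 == 1, 10 + (fr - 1), 90 - (fr - 1)),
    col = 50, intensity = 1
  )
  tr2 <- link_trajectories(drift, max_disp = 3)
  expect_identical(length(unique(tr2$trajectory_id)), 2L)
  t1 <- tr2[tr2$trajectory_id == 1, ]
  expect_equal(t1$row, 10 + 0:49)
  # a gap longer than `memory` splits the trajectory ...
  gap <- data.frame(frame = c(1:10, 13:20), row = 5, col = 5, intensity = 1)
  expect_identical(length(unique(link_trajectories(gap, 3, memory = 1)$trajectory_id)), 2L)
  # ... but a gap within `memory` is bridged
  expect_identical(length(unique(link_trajectories(gap, 3, memory = 2)$trajectory_id)), 1L)
  expect_error(link_trajectories(still, max_disp = 0), "positive")
})

test_that("trajectory_to_angles composes the geometry mapping and unwraps chi", {
  w <- dxt_world()
  # static trajectory -> constant angles
  still <- data.frame(trajectory_id = 1L, frame = 1:5, row = 120.5, col = 80.5,
                      intensity = 1)
  a <- trajectory_to_angles(still, w$geom)
  expect_equal(length(unique(a$theta)), 1L)
  # radial motion along the centre row: chi constant, theta monotone
  rad <- data.frame(trajectory_id = 1L, frame = 1:20, row = 100.5,
                    col = 110.5 + (1:20), intensity = 1)
  ar <- trajectory_to_angles(rad, w$geom)
  expect_equal(ar$chi, rep(0, 20))
  expect_true(all(diff(ar$theta) > 0))
  # pointwise oracle: theta is half the scattering angle
  oracle <- pixel_to_angles(cbind(rad$row, rad$col), w$geom)
  expect_lt(max(abs(ar$theta - oracle[, "two_theta"] / 2)), 1e-12)
  # crossing the +/- pi seam leaves no 2 pi jumps
  ang <- seq(pi - 0.2, pi + 0.2, length.out = 21)
  seam <- data.frame(trajectory_id = 1L, frame = 1:21,
                     row = 100.5 + 50 * sin(ang), col = 100.5 + 50 * cos(ang),
                     intensity = 1)
  as_ <- trajectory_to_angles(seam, w$geom)
  expect_lt(max(abs(diff(as_$chi))), 0.1)
  # leaving the detector errors
  out <- data.frame(trajectory_id = 1L, frame = 1:2, row = c(10, 300), col = 10,
                    intensity = 1)
  expect_error(trajectory_to_angles(out, w$geom), "bounds")
})

test_that("angular_displacements pools fixed-lag steps per trajectory", {
  tab <- data.frame(trajectory_id = 1L, frame = 1:50,
                    theta = 0.002 * (1:50), chi = 0.1, intensity = 1)
  expect_equal(angular_displacements(tab, "chi", lag = 1),
               rep(0, 49))
  expect_equal(angular_displacements(tab, "theta", lag = 1),
               rep(0.002, 49), tolerance = 1e-12)
  expect_equal(angular_displacements(tab, "theta", lag = 5),
               rep(0.01, 45), tolerance = 1e-12)
  # speed mode: |delta| / (lag * frame time)
  expect_equal(angular_displacements(tab, "theta", lag = 2, mode = "speed",
                                     frame_time = 0.01),
               rep(0.002 / 0.01, 48), tolerance = 1e-12)
  # gaps contribute no samples across the gap
  gap <- tab[tab$frame != 25, ]
  expect_length(angular_displacements(gap, "theta", lag = 1), 47)
  expect_error(angular_displacements(tab[1:2, ], "theta", lag = 5), "lag")
  # Brownian variance recovery at lag 1 on simulated orientation tracks
  d <- 4e-6
  gt <- simulate_orientations(10, d, 0.01, 1000, seed = 31)
  sim_tab <- data.frame(
    trajectory_id = rep(1:10, each = 1001),
    frame = rep(1:1001, 10),
    theta = as.vector(gt$theta), chi = as.vector(gt$chi)
  )
  v <- var(angular_displacements(sim_tab, "theta", lag = 1))
  expect_equal(v, 2 * d * 0.01, tolerance = 0.1)
})

test_that("fit_gaussian_peak recovers histogram peaks", {
  set.seed(32)
  x <- rnorm(10000, 0, 1e-3)
  st <- fit_gaussian_peak(x)
  expect_lt(abs(st$mu), 5e-5)
  expect_equal(st$sigma, 1e-3, tolerance = 0.05)
  expect_equal(st$peak, st$mu)
  # histogram is a probability density
  h <- st$histogram
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)
  # symmetric two-sided samples centre at zero
  sym <- rep(c(-2e-3, 2e-3), 100) + rep(c(-1e-4, 1e-4), each = 100)
  ssym <- fit_gaussian_peak(sym, n_bins = 10)
  expect_lt(abs(ssym$mu), 1e-4)
  # degenerate distribution reports sigma 0 without a fit
  dg <- fit_gaussian_peak(rep(0.5, 60))
  expect_true(dg$degenerate)
  expect_identical(dg$sigma, 0)
  expect_identical(dg$peak, 0.5)
  expect_error(fit_gaussian_peak(rnorm(10)), "50")
})

test_that("compare_conditions tabulates and round-trips through CSV", {
  set.seed(33)
  mk <- function(mu) list(
    theta = fit_gaussian_peak(rnorm(500, mu, 1e-3)),
    chi = fit_gaussian_peak(rnorm(500, 2 * mu, 2e-3))
  )
  tab <- compare_conditions(list(`5C` = mk(1e-3), `25C` = mk(2e-3), `45C` = mk(3e-3)))
  expect_identical(nrow(tab), 3L)
  expect_true(all(diff(tab$E_theta) > 0))
  one <- compare_conditions(list(only = mk(0)))
  expect_identical(nrow(one), 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_full(tab, path)
  back <- read_csv_full(path)
  expect_equal(back$E_theta, tab$E_theta)
  expect_identical(back$condition, tab$condition)
  expect_error(compare_conditions(list()), "one condition")
})
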