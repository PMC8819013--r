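# DXT analysis: spot detection (local maxima + sub-pixel centroid),
# frame-to-frame greedy nearest-neighbour linking with gap bridging,
# conversion of trajectories to (theta, chi) angular tracks, fixed-lag
# angular-displacement samples, and Gaussian peak statistics E_theta/E_chi.

#' Detect diffraction spots in one frame
#'
#' Local maxima above `threshold` are refined to sub-pixel precision by an
#' intensity-weighted centroid over a `(2k+1)^2` window (background-floor
#' subtracted). Maxima closer than `min_separation` are merged, keeping the
#' brighter one.
#'
#' @param frame 2-D counts matrix.
#' @param threshold Detection threshold in counts. Default: `median + 5 MAD`
#'   of the frame.
#' @param min_separation Minimum distance between detections, pixels.
#' @param centroid_halfwidth Half-width `k` of the centroid window.
#' @param background Constant background level subtracted (floored at 0)
#'   before the centroid; default the frame median.
#' @return `data.frame(row, col, intensity)` (possibly 0 rows); positions
#'   are continuous pixel coordinates, `intensity` the background-subtracted
#'   windowed sum.
#' @export
detect_spots <- function(frame, threshold = NULL, min_separation = 5,
                         centroid_halfwidth = 3, background = NULL) {
  stopifnot(is.matrix(frame))
  if (is.null(background)) background <- median(frame)
  if (is.null(threshold)) threshold <- median(frame) + 5 * mad(frame)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  nr <- nrow(frame); nc <- ncol(frame)
  k <- as.integer(centroid_halfwidth)
  # strict local maxima over the 8-neighbourhood (ties broken towards the
  # top-left by >= on the trailing neighbours)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- frame
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  is_max <- ctr > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    cmp <- if (dr < 0 || (dr == 0 && dc < 0)) ctr > nb else ctr >= nb
    is_max <- is_max & cmp
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(row = numeric(), col = numeric(), intensity = numeric()))
  }
  peak_val <- frame[idx]
  # merge maxima closer than min_separation, brighter wins
  ord <- order(peak_val, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1):nrow(idx)
      d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
      keep[j[d2 < min_separation^2]] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  out <- matrix(0, nrow(idx), 3)
  for (i in seq_len(nrow(idx))) {
    r0 <- idx[i, 1]; c0 <- idx[i, 2]
    rr <- max(1, r0 - k):min(nr, r0 + k)
    cc <- max(1, c0 - k):min(nc, c0 + k)
    w <- pmax(frame[rr, cc, drop = FALSE] - background, 0)
    s <- sum(w)
    if (s <= 0) {
      out[i, ] <- c(r0, c0, 0)
    } else {
      out[i, ] <- c(
        sum(rowSums(w) * rr) / s,
        sum(colSums(w) * cc) / s,
        s
      )
    }
  }
  out <- out[out[, 3] > 0, , drop = FALSE]
  ord2 <- order(out[, 1], out[, 2])
  data.frame(row = out[ord2, 1], col = out[ord2, 2], intensity = out[ord2, 3])
}

#' Detect spots in every frame of a movie
#'
#' @param movie A [diffraction_movie()].
#' @inheritParams detect_spots
#' @return `data.frame(frame, row, col, intensity)` pooled over frames.
#' @export
detect_spots_movie <- function(movie, threshold = NULL, min_separation = 5,
                               centroid_halfwidth = 3, background = NULL) {
  stopifnot(inherits(movie, "diffraction_movie"))
  res <- lapply(seq_len(n_frames(movie)), function(f) {
    s <- detect_spots(movie$counts[, , f], threshold, min_separation,
                      centroid_halfwidth, background)
    if (nrow(s)) cbind(frame = f, s) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                      intensity = numeric())
  }
  out
}

#' Link per-frame spot detections into trajectories
#'
#' Greedy nearest-neighbour assignment: candidate (track, spot) pairs within
#' `max_disp` pixels are matched in order of increasing distance; unmatched
#' spots start new trajectories; a track may bridge up to `memory` missing
#' frames before it is closed.
#'
#' @param spots `data.frame(frame, row, col, intensity)` as from
#'   [detect_spots_movie()].
#' @param max_disp Maximum frame-to-frame displacement, pixels (> 0).
#' @param memory Maximum number of consecutive missing frames bridged
#'   (>= 0).
#' @return A `spot_trajectories` object: `data.frame(trajectory_id, frame,
#'   row, col, intensity)` sorted by (trajectory_id, frame).
#' @export
link_trajectories <- function(spots, max_disp, memory = 0) {
  if (max_disp <= 0) stop("`max_disp` must be positive", call. = FALSE)
  if (memory < 0) stop("`memory` must be >= 0", call. = FALSE)
  if (!all(c("frame", "row", "col") %in% names(spots))) {
    stop("`spots` needs columns frame, row, col", call. = FALSE)
  }
  if (is.null(spots$intensity)) spots$intensity <- NA_real_
  spots <- spots[order(spots$frame), , drop = FALSE]
  n <- nrow(spots)
  traj_id <- integer(n)
  # active tracks: id, last row/col, last frame
  act_id <- integer(0); act_r <- numeric(0); act_c <- numeric(0); act_f <- integer(0)
  next_id <- 1L
  for (f in unique(spots$frame)) {
    rows_f <- which(spots$frame == f)
    alive <- f - act_f <= memory + 1L
    act_id <- act_id[alive]; act_r <- act_r[alive]
    act_c <- act_c[alive]; act_f <- act_f[alive]
    m <- length(rows_f); a <- length(act_id)
    assigned_spot <- rep(FALSE, m)
    assigned_trk <- rep(FALSE, a)
    if (a > 0 && m > 0) {
      dr <- outer(act_r, spots$row[rows_f], "-")
      dc <- outer(act_c, spots$col[rows_f], "-")
      dist <- sqrt(dr^2 + dc^2)
      cand <- which(dist <= max_disp, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dist[cand]), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          ti <- cand[i, 1]; si <- cand[i, 2]
          if (assigned_trk[ti] || assigned_spot[si]) next
          assigned_trk[ti] <- TRUE
          assigned_spot[si] <- TRUE
          traj_id[rows_f[si]] <- act_id[ti]
          act_r[ti] <- spots$row[rows_f[si]]
          act_c[ti] <- spots$col[rows_f[si]]
          act_f[ti] <- f
        }
      }
    }
    new_spots <- which(!assigned_spot)
    if (length(new_spots)) {
      ids <- next_id + seq_along(new_spots) - 1L
      next_id <- next_id + length(new_spots)
      traj_id[rows_f[new_spots]] <- ids
      act_id <- c(act_id, ids)
      act_r <- c(act_r, spots$row[rows_f[new_spots]])
      act_c <- c(act_c, spots$col[rows_f[new_spots]])
      act_f <- c(act_f, rep(f, length(new_spots)))
    }
  }
  out <- data.frame(
    trajectory_id = traj_id, frame = spots$frame,
    row = spots$row, col = spots$col, intensity = spots$intensity
  )
  out <- out[order(out$trajectory_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spot_trajectories", "data.frame")
  out
}

#' Trajectory duration summary
#' @param traj A [link_trajectories()] result.
#' @return `data.frame(trajectory_id, n_points, first_frame, last_frame)`.
#' @export
trajectory_durations <- function(traj) {
  sp <- split(traj$frame, traj$trajectory_id)
  data.frame(
    trajectory_id = as.integer(names(sp)),
    n_points = vapply(sp, length, integer(1)),
    first_frame = vapply(sp, min, numeric(1)),
    last_frame = vapply(sp, max, numeric(1)),
    row.names = NULL
  )
}

#' Convert pixel trajectories to angular tracks
#'
#' Maps every trajectory point through the detector geometry: `theta` is the
#' Bragg half-angle (half the scattering angle 2theta of the pixel), `chi`
#' the azimuth. Within each trajectory `chi` is unwrapped across the +/- pi
#' seam so that displacements are continuous.
#'
#' @param traj A [link_trajectories()] result (or data.frame with
#'   trajectory_id, frame, row, col).
#' @param geom A [detector_geometry()].
#' @return The input with `theta` and `chi` columns appended (radians).
#' @export
trajectory_to_angles <- function(traj, geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  if (any(traj$row < 0.5 | traj$row > geom$n_rows + 0.5 |
          traj$col < 0.5 | traj$col > geom$n_cols + 0.5)) {
    stop("trajectory leaves the detector bounds", call. = FALSE)
  }
  ang <- pixel_to_angles(cbind(traj$row, traj$col), geom)
  traj$theta <- ang[, "two_theta"] / 2
  traj$chi <- ang[, "chi"]
  for (id in unique(traj$trajectory_id)) {
    i <- which(traj$trajectory_id == id)
    traj$chi[i] <- unwrap_angle(traj$chi[i])
  }
  traj
}

# remove 2*pi jumps from an angle series (standard phase unwrap)
unwrap_angle <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  d <- d - 2 * pi * round(d / (2 * pi))
  x[1] + c(0, cumsum(d))
}

#' Fixed-lag angular displacement samples
#'
#' Pools, across trajectories, the displacements of `theta` or `chi` over a
#' fixed lag. Only frame pairs exactly `lag` apart within the same trajectory
#' contribute (gaps are skipped). `signed` mode returns the raw displacement
#' in radians; `speed` mode returns `|displacement| / (lag * frame_time)` in
#' rad/s.
#'
#' @param traj An angular track table from [trajectory_to_angles()].
#' @param direction `"theta"` or `"chi"`.
#' @param lag Lag in frames (>= 1).
#' @param mode `"signed"` or `"speed"`.
#' @param frame_time Frame interval in seconds (required for `speed` mode).
#' @return Numeric vector of displacement samples.
#' @export
angular_displacements <- function(traj, direction = c("theta", "chi"), lag = 1,
                                  mode = c("signed", "speed"), frame_time = NULL) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  lag <- as.integer(lag)
  if (lag < 1L) stop("`lag` must be >= 1", call. = FALSE)
  if (mode == "speed" && is.null(frame_time)) {
    stop("`frame_time` is required for speed mode", call. = FALSE)
  }
  val <- traj[[direction]]
  if (is.null(val)) stop("run trajectory_to_angles() first", call. = FALSE)
  samples <- unlist(lapply(split(seq_len(nrow(traj)), traj$trajectory_id), function(i) {
    fr <- traj$frame[i]
    o <- order(fr)
    fr <- fr[o]; v <- val[i][o]
    tgt <- match(fr + lag, fr)
    ok <- !is.na(tgt)
    v[tgt[ok]] - v[ok]
  }), use.names = FALSE)
  if (!length(samples)) {
    stop("no trajectory is longer than the requested lag", call. = FALSE)
  }
  if (mode == "speed") abs(samples) / (lag * frame_time) else samples
}

#' Gaussian fit of a displacement histogram
#'
#' Bins the samples into a probability-density histogram (Freedman-Diaconis
#' by default) and least-squares fits a Gaussian
#' `a exp(-(x - mu)^2 / (2 sigma^2))` to the bin centres and densities. The
#' reported `peak` is the fitted mean (the Gaussian is symmetric).
#'
#' @param samples Numeric displacement samples (>= 50 unless degenerate).
#' @param n_bins Number of histogram bins; default Freedman-Diaconis.
#' @return An `angular_stats` object: `mu`, `sigma`, `peak`, `amplitude`,
#'   `n`, `histogram` (list: breaks, mids, density), `degenerate` flag.
#' @export
fit_gaussian_peak <- function(samples, n_bins = NULL) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 2L || var(samples) == 0) {
    return(structure(
      list(mu = samples[1], sigma = 0, peak = samples[1], amplitude = NA_real_,
           n = n, histogram = NULL, degenerate = TRUE),
      class = "angular_stats"
    ))
  }
  if (n < 50L) stop("need at least 50 samples for a histogram fit", call. = FALSE)
  if (is.null(n_bins)) {
    bw <- 2 * IQR(samples) / n^(1 / 3)  # Freedman-Diaconis
    n_bins <- max(10L, ceiling(diff(range(samples)) / bw))
  }
  h <- hist(samples, breaks = seq(min(samples), max(samples), length.out = n_bins + 1),
            plot = FALSE)
  x <- h$mids; d <- h$density
  mu0 <- mean(samples); s0 <- sd(samples); a0 <- max(d)
  sse <- function(p) {
    r <- p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) - d
    sum(r * r)
  }
  fit <- optim(c(a0, mu0, s0), sse, method = "L-BFGS-B",
               lower = c(1e-12, -Inf, 1e-12 * s0),
               control = list(maxit = 1000))
  structure(
    list(mu = fit$par[2], sigma = fit$par[3], peak = fit$par[2],
         amplitude = fit$par[1], n = n,
         histogram = list(breaks = h$breaks, mids = h$mids, density = h$density),
         degenerate = FALSE),
    class = "angular_stats"
  )
}

#' @export
print.angular_stats <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<angular_stats> degenerate: all %d samples = %g\n", x$n, x$mu))
  } else {
    cat(sprintf(
      "<angular_stats> peak (mu) = %.4g rad, sigma = %.4g rad (n = %d)\n",
      x$peak, x$sigma, x$n
    ))
  }
  invisible(x)
}

#' Tabulate angular-displacement peaks across conditions
#'
#' Collects the Gaussian peak statistics of the theta and chi displacement
#' distributions for each experimental condition (e.g. temperature) into a
#' tidy table for plotting or export.
#'
#' @param stats_by_condition Named list; each element is
#'   `list(theta = angular_stats, chi = angular_stats)`.
#' @return `data.frame(condition, E_theta, E_chi, sigma_theta, sigma_chi,
#'   n_theta, n_chi)`.
#' @export
compare_conditions <- function(stats_by_condition) {
  if (!length(stats_by_condition)) stop("need at least one condition", call. = FALSE)
  rows <- lapply(names(stats_by_condition), function(nm) {
    s <- stats_by_condition[[nm]]
    data.frame(
      condition = nm,
      E_theta = s$theta$peak, E_chi = s$chi$peak,
      sigma_theta = s$theta$sigma, sigma_chi = s$chi$sigma,
      n_theta = s$theta$n, n_chi = s$chi$n
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
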