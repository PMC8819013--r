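# DXB analysis: per-pixel intensity autocorrelation, constrained exponential
# fitting with the acceptance conditions (I) A, Gamma, y > 0 and
# (II) residual < 1, decay-constant maps/distributions, and the conversion
# D_R = phi_theta^2 * Gamma / 4 to a rotational diffusion coefficient.

#' Intensity autocorrelation of a pixel trace
#'
#' `ACF(tau) = < I(t) I(t + tau) > / < I(t) >^2`, where the numerator
#' averages over the overlapping window `t = 1 .. N - tau` and the
#' denominator uses the FULL-trace mean (one number, used for every lag).
#' Lag 0 is excluded; lags run from one frame interval to `max_lag`.
#'
#' @param trace Numeric vector of per-frame counts (length >= 2 * max_lag).
#' @param max_lag Maximum lag in frames (default `floor(N / 4)`).
#' @param dt Frame interval in seconds (default 1: lags in frame units).
#' @return An object of class `acf_curve`: `lags` (s), `values`, and
#'   `n_frames_used`.
#' @export
compute_acf <- function(trace, max_lag = NULL, dt = 1) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (is.null(max_lag)) max_lag <- max(1L, n %/% 4L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("`max_lag` must be >= 1", call. = FALSE)
  if (n < 2L * max_lag) {
    stop(sprintf("trace too short: need >= %d frames for max_lag = %d", 2L * max_lag, max_lag),
         call. = FALSE)
  }
  m <- mean(trace)
  if (m <= 0) stop("undefined ACF: trace mean must be positive", call. = FALSE)
  vals <- vapply(seq_len(max_lag), function(k) {
    mean(trace[1:(n - k)] * trace[(k + 1):n])
  }, numeric(1)) / m^2
  structure(
    list(lags = seq_len(max_lag) * dt, values = vals, n_frames_used = n),
    class = "acf_curve"
  )
}

#' Fit a decaying exponential to an ACF curve
#'
#' Least-squares fit of `ACF(t) = A exp(-Gamma t) + y` by bounded L-BFGS-B,
#' parameters constrained to `[lower, upper]` (default non-negative). The fit
#' is accepted only when (I) all of `A`, `Gamma`, `y` are strictly positive
#' and (II) the residual metric is below 1.0. The residual is the RMS
#' deviation between fitted and empirical curve divided by the standard
#' deviation of the empirical curve (dimensionless); for a constant empirical
#' curve it is 0 for a perfect fit and `Inf` otherwise. Fitted parameters are
#' returned whether or not the fit is accepted; optimiser failure is reported
#' via `accepted = FALSE` with a diagnostic, never an error.
#'
#' @param curve An [compute_acf()] result (>= 4 lag points).
#' @param init Optional `c(A, gamma, y)` starting values. Default: amplitude
#'   and offset from the curve ends, `Gamma` from the lag where the curve
#'   first crosses `y0 + A0 / e`.
#' @param lower,upper Parameter bounds for `(A, gamma, y)`.
#' @param max_iter Maximum optimiser iterations.
#' @return An object of class `acf_fit`: `A`, `gamma`, `y`, `residual`,
#'   `accepted`, `conditions` (logical, `positivity` and `residual`),
#'   `reason` (NULL or character).
#' @export
fit_acf <- function(curve, init = NULL, lower = c(0, 0, 0),
                    upper = c(Inf, Inf, Inf), max_iter = 1000) {
  stopifnot(inherits(curve, "acf_curve"))
  tau <- curve$lags
  v <- curve$values
  if (length(tau) < 4L) stop("need at least 4 lag points to fit", call. = FALSE)
  if (is.null(init)) {
    a0 <- v[1] - v[length(v)]
    y0 <- v[length(v)]
    if (a0 <= 0) a0 <- max(abs(a0), 0.1 * max(abs(v), 1e-8))
    thresh <- y0 + a0 / exp(1)
    cross <- which(v <= thresh)
    g0 <- if (length(cross)) 1 / tau[cross[1]] else 1 / tau[ceiling(length(tau) / 2)]
    init <- c(a0, g0, max(y0, 0))
  }
  init <- pmin(pmax(init, lower), upper)
  sse <- function(p) {
    r <- p[1] * exp(-p[2] * tau) + p[3] - v
    sum(r * r)
  }
  grad <- function(p) {
    e <- exp(-p[2] * tau)
    r <- p[1] * e + p[3] - v
    2 * c(sum(r * e), -p[1] * sum(r * e * tau), sum(r))
  }
  fitp <- init
  reason <- NULL
  res <- tryCatch(
    optim(init, sse, grad, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = max_iter, factr = 10, pgtol = 0)),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    reason <- paste("optimiser error:", conditionMessage(res))
  } else {
    fitp <- res$par
    if (res$convergence != 0) {
      reason <- sprintf("optimiser did not converge (code %d): %s",
                        res$convergence, res$message %||% "")
    }
  }
  fitted <- fitp[1] * exp(-fitp[2] * tau) + fitp[3]
  rms <- sqrt(mean((fitted - v)^2))
  sdv <- sd(v)
  residual <- if (sdv > 0) rms / sdv else if (rms < 1e-12) 0 else Inf
  cond1 <- fitp[1] > 0 && fitp[2] > 0 && fitp[3] > 0
  cond2 <- is.finite(residual) && residual < 1.0
  accepted <- cond1 && cond2 && is.null(reason)
  structure(
    list(
      A = fitp[1], gamma = fitp[2], y = fitp[3],
      residual = residual, accepted = accepted,
      conditions = c(positivity = cond1, residual = cond2),
      reason = reason
    ),
    class = "acf_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf(
    "<acf_fit> A = %.4g, Gamma = %.4g /s, y = %.4g, residual = %.3g [%s]\n",
    x$A, x$gamma, x$y, x$residual, if (x$accepted) "accepted" else "rejected"
  ))
  if (!is.null(x$reason)) cat("  ", x$reason, "\n")
  invisible(x)
}

#' Per-pixel decay-constant map over a diffraction ring
#'
#' For every ring pixel whose temporal mean is at least `min_mean`, computes
#' the intensity ACF and the constrained exponential fit, collects the decay
#' constants of accepted fits, and summarises their distribution (median and
#' quartiles by linear interpolation).
#'
#' @param movie A [diffraction_movie()].
#' @param ring A [ring_mask()] on the same detector shape.
#' @param max_lag Maximum ACF lag in frames (default `n_frames / 4`), or
#'   `"adaptive"`: per pixel, an initial fit at `n_frames / 4` sets the lag
#'   window to about `adapt_decades / gamma`, and the fit is repeated (two
#'   passes). The adaptive window makes the estimator scale-equivariant: a
#'   movie whose dynamics are uniformly sped up by a factor s yields s-times
#'   larger decay constants instead of a window-limited compromise, which is
#'   what comparisons across diffusion coefficients need.
#' @param min_mean Minimum temporal mean (counts/frame) for a pixel to be
#'   analysed. Default 5.
#' @param adapt_decades Target extent of the adaptive window in units of the
#'   fitted decay time `1 / gamma` (default 3).
#' @return An object of class `decay_map`: `gamma_map` (matrix, `NaN` where
#'   absent), `table` (data.frame: row, col, mean_intensity, A, gamma, y,
#'   residual, accepted), and `distribution` (gammas, median, q1, q3,
#'   n_accepted, n_rejected).
#' @export
decay_map <- function(movie, ring, max_lag = NULL, min_mean = 5,
                      adapt_decades = 3) {
  stopifnot(inherits(movie, "diffraction_movie"), inherits(ring, "ring_selection"))
  d <- dim(movie$counts)
  if (d[1] != ring$n_rows || d[2] != ring$n_cols) {
    stop("movie and ring selection have different detector shapes", call. = FALSE)
  }
  nf <- d[3]
  adaptive <- identical(max_lag, "adaptive")
  if (is.null(max_lag) || adaptive) max_lag <- max(1L, nf %/% 4L)
  px <- ring$pixels
  means <- vapply(seq_len(nrow(px)), function(i) {
    mean(movie$counts[px[i, 1], px[i, 2], ])
  }, numeric(1))
  use <- means >= min_mean & means > 0
  px_use <- px[use, , drop = FALSE]
  n_use <- nrow(px_use)
  rows <- vector("list", n_use)
  reject_tally <- c(positivity = 0L, residual = 0L, other = 0L)
  for (i in seq_len(n_use)) {
    tr <- movie$counts[px_use[i, 1], px_use[i, 2], ]
    fit <- fit_acf(compute_acf(tr, max_lag = max_lag, dt = movie$exposure))
    if (adaptive) {
      # iterate window <- adapt_decades / gamma to its fixed point so the
      # lag range tracks the decay time whatever its magnitude
      lag_cur <- max_lag
      for (pass in 1:6) {
        if (!(fit$gamma > 0) || !is.finite(fit$gamma)) break
        lag_new <- ceiling(adapt_decades / (fit$gamma * movie$exposure))
        lag_new <- min(max(lag_new, 8L), nf %/% 4L)
        if (lag_new == lag_cur) break
        lag_cur <- lag_new
        fit <- fit_acf(compute_acf(tr, max_lag = lag_cur, dt = movie$exposure))
      }
    }
    if (!fit$accepted) {
      if (!fit$conditions[["positivity"]]) {
        reject_tally[["positivity"]] <- reject_tally[["positivity"]] + 1L
      } else if (!fit$conditions[["residual"]]) {
        reject_tally[["residual"]] <- reject_tally[["residual"]] + 1L
      } else {
        reject_tally[["other"]] <- reject_tally[["other"]] + 1L
      }
    }
    rows[[i]] <- data.frame(
      row = px_use[i, 1], col = px_use[i, 2], mean_intensity = means[use][i],
      A = fit$A, gamma = fit$gamma, y = fit$y,
      residual = fit$residual, accepted = fit$accepted
    )
  }
  tab <- if (n_use) do.call(rbind, rows) else
    data.frame(row = integer(), col = integer(), mean_intensity = numeric(),
               A = numeric(), gamma = numeric(), y = numeric(),
               residual = numeric(), accepted = logical())
  if (!any(tab$accepted)) {
    stop(sprintf(
      paste0("no ring pixel produced an accepted fit ",
             "(%d analysed; rejected: %d positivity, %d residual, %d other)"),
      n_use, reject_tally[["positivity"]], reject_tally[["residual"]],
      reject_tally[["other"]]
    ), call. = FALSE)
  }
  gammas <- tab$gamma[tab$accepted]
  gmap <- matrix(NaN, d[1], d[2])
  acc <- tab[tab$accepted, ]
  gmap[cbind(acc$row, acc$col)] <- acc$gamma
  q <- unname(quantile(gammas, c(0.25, 0.5, 0.75), type = 7))
  structure(
    list(
      gamma_map = gmap,
      table = tab,
      distribution = list(
        gammas = gammas, q1 = q[1], median = q[2], q3 = q[3],
        n_accepted = sum(tab$accepted), n_rejected = sum(!tab$accepted)
      ),
      max_lag = max_lag, min_mean = min_mean
    ),
    class = "decay_map"
  )
}

#' @export
print.decay_map <- function(x, ...) {
  d <- x$distribution
  cat(sprintf(
    "<decay_map> %d accepted / %d rejected pixels; Gamma median %.4g /s (IQR %.4g-%.4g)\n",
    d$n_accepted, d$n_rejected, d$median, d$q1, d$q3
  ))
  invisible(x)
}

#' Rotational diffusion coefficient from an ACF decay constant
#'
#' `D_R = phi_theta^2 * Gamma / 4`, with `phi_theta` the angular width of the
#' analysed ring in 2theta. Supplying a lever-arm `radius` converts the
#' angular coefficient to arc-length units (`D_R * radius^2`, in
#' `radius`-unit^2 per second); no canonical radius is assumed.
#'
#' @param gamma Decay constant(s), 1/s (>= 0).
#' @param phi_theta Ring angular width, radians (> 0).
#' @param radius Optional lever-arm radius; output then has units of
#'   `radius^2` per second (e.g. pm^2/s for a radius in pm).
#' @return Rotational diffusion coefficient, rad^2/s (or arc-length units).
#' @export
rotational_diffusion <- function(gamma, phi_theta, radius = NULL) {
  if (any(gamma < 0)) stop("`gamma` must be >= 0", call. = FALSE)
  if (phi_theta <= 0) stop("`phi_theta` must be positive", call. = FALSE)
  d <- phi_theta^2 * gamma / 4
  if (!is.null(radius)) d <- d * radius^2
  d
}

#' Integrated ring intensity
#'
#' Sum of counts over the ring pixels, per frame and in total; the
#' labelled-vs-control comparison statistic.
#'
#' @param movie A [diffraction_movie()].
#' @param ring A [ring_mask()] on the same detector shape.
#' @return `list(per_frame = numeric(n_frames), total = numeric(1))`.
#' @export
integrate_ring_intensity <- function(movie, ring) {
  stopifnot(inherits(movie, "diffraction_movie"), inherits(ring, "ring_selection"))
  d <- dim(movie$counts)
  if (d[1] != ring$n_rows || d[2] != ring$n_cols) {
    stop("movie and ring selection have different detector shapes", call. = FALSE)
  }
  flat <- matrix(movie$counts, d[1] * d[2], d[3])
  per_frame <- colSums(flat[as.vector(ring$mask), , drop = FALSE])
  list(per_frame = per_frame, total = sum(per_frame))
}
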