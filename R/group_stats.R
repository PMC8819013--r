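# Two-sample comparisons used for the figure-level group contrasts:
# Brunner-Munzel nonparametric test (boxplot-style decay-constant
# distributions), pooled-variance Student's t (integrated ring intensities),
# and the quartile/whisker boxplot summary.

#' Brunner-Munzel two-sample test
#'
#' Nonparametric test of the relative effect
#' `p = P(X < Y) + 0.5 P(X = Y)` estimated with pooled mid-ranks (ties
#' handled by mid-ranks). The studentised statistic uses the Brunner-Munzel
#' variance estimator and a Welch-type t reference distribution (two-sided).
#' When both rank variances are zero (e.g. identical constant samples) the
#' comparison carries no evidence: the result is `statistic = 0, p = 1` with
#' `degenerate = TRUE` rather than an error.
#'
#' @param x,y Numeric sample vectors. A warning is issued below 10
#'   observations per group (the t approximation is a large-sample one).
#' @return A `test_result` list: `statistic`, `p_value`, `df`,
#'   `relative_effect`, `n1`, `n2`, `method`, `degenerate`.
#' @export
brunner_munzel <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group", call. = FALSE)
  if (n1 < 10L || n2 < 10L) {
    warning("Brunner-Munzel t approximation is unreliable below n = 10 per group")
  }
  r_all <- rank(c(x, y), ties.method = "average")
  r1 <- r_all[seq_len(n1)]
  r2 <- r_all[n1 + seq_len(n2)]
  r1w <- rank(x, ties.method = "average")
  r2w <- rank(y, ties.method = "average")
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  s1sq <- sum((r1 - r1w - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  s2sq <- sum((r2 - r2w - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  sig <- n1 * s1sq + n2 * s2sq
  n <- n1 + n2
  if (sig <= 0) {
    res <- list(statistic = 0, p_value = 1, df = NA_real_,
                relative_effect = p_hat, n1 = n1, n2 = n2,
                method = "Brunner-Munzel", degenerate = TRUE)
    class(res) <- "test_result"
    return(res)
  }
  statistic <- n1 * n2 * (m2 - m1) / (n * sqrt(sig))
  df <- sig^2 / ((n1 * s1sq)^2 / (n1 - 1) + (n2 * s2sq)^2 / (n2 - 1))
  p <- 2 * pt(-abs(statistic), df)
  structure(
    list(statistic = statistic, p_value = p, df = df,
         relative_effect = p_hat, n1 = n1, n2 = n2,
         method = "Brunner-Munzel", degenerate = FALSE),
    class = "test_result"
  )
}

#' Student's two-sample t-test (pooled variance)
#'
#' `t = (mean(x) - mean(y)) / (s_p sqrt(1/n1 + 1/n2))` with the pooled
#' standard deviation `s_p`; two-sided p from `df = n1 + n2 - 2`.
#'
#' @param x,y Numeric sample vectors (>= 2 each).
#' @return A `test_result` list (as [brunner_munzel()], without
#'   `relative_effect`).
#' @export
student_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  if (sp2 <= 0) {
    if (mean(x) == mean(y)) {
      res <- list(statistic = 0, p_value = 1, df = df,
                  relative_effect = NULL, n1 = n1, n2 = n2,
                  method = "Student t (pooled)", degenerate = TRUE)
      class(res) <- "test_result"
      return(res)
    }
    stop("zero pooled variance with unequal means: t undefined", call. = FALSE)
  }
  statistic <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(
    list(statistic = statistic, p_value = 2 * pt(-abs(statistic), df), df = df,
         relative_effect = NULL, n1 = n1, n2 = n2,
         method = "Student t (pooled)", degenerate = FALSE),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %.4g, p = %.4g (n = %d, %d)%s\n",
              x$method, x$statistic, x$df %||% NA, x$p_value, x$n1, x$n2,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  if (!is.null(x$relative_effect)) {
    cat(sprintf("  relative effect P(X<Y)+P(X=Y)/2 = %.4g\n", x$relative_effect))
  }
  invisible(x)
}

#' Boxplot summary of a sample
#'
#' Quartiles by linear interpolation (type 7); whiskers at the most extreme
#' observations within `1.5 * IQR` of the box; points beyond flagged as
#' outliers.
#'
#' @param values Numeric vector (>= 1 value).
#' @return List: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("need at least one value", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(values[inside]), whisker_high = max(values[inside]),
    outliers = sort(values[!inside]), n = length(values)
  )
}
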