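#' Synchrony estimation error
#'
#' The measured synchrony (on 0-1) is scaled by 100 to match the 0-100
#' estimation slider, and the observer's estimate is subtracted:
#' `D = 100 * S - E`. Positive values reflect underestimation, negative
#' values overestimation. For example, measured synchrony 0.70 with an
#' estimate of 60 gives an error of 10.
#'
#' @param measured Measured synchrony in `[0, 1]` (vectorised).
#' @param estimate Estimated synchrony in `[0, 100]` (vectorised).
#' @return Numeric error on the 0-100 scale.
#' @export
estimation_error <- function(measured, estimate) {
  if (any(measured < 0 | measured > 1, na.rm = TRUE)) {
    stop("`measured` must lie in [0, 1]", call. = FALSE)
  }
  if (any(estimate < 0 | estimate > 100, na.rm = TRUE)) {
    stop("`estimate` must lie in [0, 100]", call. = FALSE)
  }
  100 * measured - estimate
}

#' Z-score a vector
#'
#' Centres and scales by the sample standard deviation (n - 1 denominator),
#' the standardisation applied to all trait and kinematic predictors before
#' modelling.
#'
#' @param x Numeric vector, length >= 2, non-zero variance.
#' @return Standardised vector with mean 0 and SD 1.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to z-score", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a zero-variance vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted sample values — the empirical HPD interval used for all posterior
#' summaries. Never wider than the equal-tailed interval of the same mass.
#'
#' @param samples Numeric vector of posterior draws (>= 100).
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (length(samples) < 100) {
    stop("need at least 100 samples for an HPD interval", call. = FALSE)
  }
  if (mass <= 0 || mass >= 1) stop("`mass` must be in (0, 1)", call. = FALSE)
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) {
    return(c(lower = s[1], upper = s[n]))
  }
  starts <- 1:(n - k + 1)
  widths <- s[starts + k - 1] - s[starts]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + k - 1])
}
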