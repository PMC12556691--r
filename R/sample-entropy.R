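#' Sample entropy of a time series
#'
#' SampEn(m, r) = -ln(A / B), where B counts pairs of length-`m` templates
#' and A pairs of length-`m + 1` templates whose Chebyshev distance is at
#' most `r`, with self-matches excluded. Both counts run over the first
#' `n - m` template start points, so every length-`m` template has a
#' length-`m + 1` continuation. The tolerance defaults to
#' `r_factor * sd(x)`. Values near 0 indicate a regular, "pure" signal;
#' larger values indicate irregularity.
#'
#' Edge cases: a constant series returns 0; if no (m+1)-template pair
#' matches (A = 0) the function returns `Inf`.
#'
#' @param x Numeric series of length >= m + 2.
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of `sd(x)` (default 0.2).
#' @param r Absolute tolerance; overrides `r_factor` when given.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, r = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < m + 2) {
    stop(sprintf("series of length %d too short for sample entropy with m = %d (need >= %d)",
      n, m, m + 2
    ), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("series must be finite", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(0)
  }
  if (is.null(r)) r <- r_factor * stats::sd(x)
  nt <- n - m # template start points
  # Chebyshev distances accumulated component-wise over m, then m+1 lags
  cheb <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    xk <- x[(1 + k):(nt + k)]
    cheb <- pmax(cheb, abs(outer(xk, xk, "-")))
  }
  b_mat <- cheb <= r
  xk <- x[(1 + m):(nt + m)]
  a_mat <- pmax(cheb, abs(outer(xk, xk, "-"))) <= r
  # exclude self-matches; count unordered pairs
  B <- (sum(b_mat) - nt) / 2
  A <- (sum(a_mat) - nt) / 2
  if (B == 0) {
    return(Inf)
  }
  if (A == 0) {
    return(Inf)
  }
  -log(A / B)
}
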