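#' Storey q-values
#'
#' Converts p-values to q-values (false-discovery-rate analogues). The
#' proportion of true nulls pi0 is estimated on a lambda grid with a cubic
#' smoothing spline evaluated at the largest lambda, clamped to (0, 1]. With
#' fewer than 100 p-values, or when the estimate is unstable, pi0 falls back
#' to 1, in which case the q-values reduce exactly to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param pi0 Optional fixed null proportion overriding estimation. `pi0 = 1`
#'   gives the Benjamini-Hochberg step-up values.
#' @param lambda Grid used for pi0 estimation.
#'
#' @return Numeric vector of q-values in the input order.
#' @examples
#' compute_qvalues(c(0.001, 0.01, 0.02, 0.8, 0.9), pi0 = 1)
#' @export
compute_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- estimate_pi0(p, lambda)
  } else {
    if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1)
      stop("pi0 must be a single value in (0, 1]")
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Estimate the null proportion pi0 from a p-value distribution
#'
#' Storey's estimator: pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) on a
#' lambda grid, smoothed with a cubic spline (df = 3) and read off at the
#' largest lambda. Returns 1 when fewer than 100 p-values are supplied or the
#' smoothed estimate is not finite.
#'
#' @inheritParams compute_qvalues
#' @return A single pi0 in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  if (m < 100) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
  if (inherits(fit, "try-error")) return(1)
  est <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(est) || est <= 0) return(1)
  min(est, 1)
}
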