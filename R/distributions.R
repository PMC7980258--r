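# Laplace distribution functions and Kolmogorov-Smirnov utilities.

#' The Laplace (bi-exponential) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Laplace distribution with location `m` and scale `b`
#' (density \eqn{\frac{1}{2b} e^{-|x-m|/b}}, variance \eqn{2b^2}).
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param m Location (median).
#' @param b Scale (> 0).
#' @return `dlaplace` the density, `plaplace` the CDF, `qlaplace` the
#'   quantile function, `rlaplace` random deviates.
#' @name laplace
NULL

#' @rdname laplace
#' @export
dlaplace <- function(x, m = 0, b = 1) exp(-abs(x - m) / b) / (2 * b)

#' @rdname laplace
#' @export
plaplace <- function(q, m = 0, b = 1) {
  z <- (q - m) / b
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}

#' @rdname laplace
#' @export
qlaplace <- function(p, m = 0, b = 1) {
  ifelse(p < 0.5, m + b * log(2 * p), m - b * log(2 * (1 - p)))
}

#' @rdname laplace
#' @export
rlaplace <- function(n, m = 0, b = 1) qlaplace(stats::runif(n), m, b)

# One-sample KS statistic of sample x against a CDF function.
ks_statistic_1s <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(pmax(abs(Fx - (seq_len(n) - 1) / n), abs(seq_len(n) / n - Fx)))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical CDFs. With
#' `normalize = TRUE`, each sample is first scaled to unit variance, the
#' convention under which velocity distributions of different overall
#' magnitude are compared on shape alone.
#'
#' @param a,b Numeric samples (nonempty).
#' @param normalize Scale each sample by its own SD before comparison.
#' @return The KS statistic in `[0, 1]`.
#' @export
ks_two_sample <- function(a, b, normalize = FALSE) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (normalize) {
    a <- a / stats::sd(a)
    b <- b / stats::sd(b)
  }
  grid <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  max(abs(Fa - Fb))
}
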