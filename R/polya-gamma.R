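#' Draw from the Polya-Gamma distribution
#'
#' Exact draws from PG(b, c) for positive integer exposure `b`, via the
#' alternating-series accept-reject sampler for PG(1, c) with `b > 1`
#' handled as a sum of independent PG(1, c) draws. Exposures in the tied
#' Bradley-Terry augmentation are per-pair comparison counts
#' `y_ij + t_ij`, so they are small integers by construction.
#'
#' Draws use R's RNG stream, so `set.seed()` makes them reproducible.
#'
#' @param b Positive integer exposure(s).
#' @param c Tilt parameter(s), any real; recycled against `b`.
#' @return Numeric vector of positive draws, one per (b, c) pair.
#' @examples
#' set.seed(1)
#' mean(sample_pg(rep(1, 1e4), 0))  # ~ 0.25
#' @export
sample_pg <- function(b, c = 0) {
  if (length(b) == 0) return(numeric(0))
  n <- max(length(b), length(c))
  b <- rep_len(b, n)
  c <- rep_len(c, n)
  if (any(!is.finite(b)) || any(b < 1) || any(b != round(b))) {
    stop("PG exposure `b` must be a positive integer", call. = FALSE)
  }
  .rpg_cpp(as.integer(b), as.numeric(c))
}

#' Mean of the Polya-Gamma distribution
#'
#' Closed form `b tanh(c/2) / (2c)`, with the `c -> 0` limit `b/4`.
#'
#' @param b Positive exposure (any positive real; the moment formula does
#'   not require integrality).
#' @param c Tilt parameter.
#' @return The mean, vectorised over inputs.
#' @export
pg_mean <- function(b, c = 0) {
  if (any(b <= 0)) stop("`b` must be positive", call. = FALSE)
  out <- ifelse(c == 0, b / 4, b * tanh(c / 2) / (2 * c))
  as.numeric(out)
}

#' Variance of the Polya-Gamma distribution
#'
#' Closed form `b (sinh(c) - c) / (4 c^3) / cosh^2(c/2)` in the
#' `sech`-normalised parameterisation; the `c -> 0` limit is `b/24`.
#'
#' @inheritParams pg_mean
#' @return The variance, vectorised.
#' @export
pg_var <- function(b, c = 0) {
  if (any(b <= 0)) stop("`b` must be positive", call. = FALSE)
  out <- ifelse(
    c == 0,
    b / 24,
    b * (sinh(c) - c) / (4 * c^3 * cosh(c / 2)^2)
  )
  as.numeric(out)
}

#' Monte-Carlo residual of the Polya-Gamma integral identity
#'
#' The augmentation rests on the identity
#' \deqn{\frac{(e^x)^a}{(1+e^x)^b} = 2^{-b} e^{(a-b/2)x}
#'   E_{z \sim PG(b,0)}[e^{-z x^2 / 2}].}
#' This helper estimates the left-hand side minus nothing: it returns the
#' Monte-Carlo estimate of the right-hand side minus the closed-form
#' left-hand side, along with the Monte-Carlo standard error, so tests
#' can assert the residual is statistically zero.
#'
#' @param a Real exponent on the numerator.
#' @param b Positive integer exposure.
#' @param x Real argument.
#' @param n_samples Number of PG(b, 0) draws.
#' @return A tibble with columns `residual`, `mc_se`, `n_samples`.
#' @export
pg_identity_residual <- function(a, b, x, n_samples = 1e5) {
  z <- sample_pg(rep(b, n_samples), 0)
  draws <- 2^(-b) * exp((a - b / 2) * x) * exp(-z * x^2 / 2)
  lhs <- exp(a * x - b * log1p(exp(x)))
  tibble::tibble(
    residual = mean(draws) - lhs,
    mc_se = stats::sd(draws) / sqrt(n_samples),
    n_samples = n_samples
  )
}
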