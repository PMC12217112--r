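#' Outcome probabilities under the tied Bradley-Terry model
#'
#' For a comparison of wards with qualities `lambda_i` and `lambda_j` and
#' tie parameter `delta >= 0`, the model assigns
#' \deqn{\pi(i \mathrm{\ beats\ } j) =
#'   e^{\lambda_i} / (e^{\lambda_i} + e^{\lambda_j + \delta}),}
#' symmetrically for j beating i, and the remaining mass
#' \deqn{\pi(\mathrm{tie}) = (e^{2\delta} - 1) e^{\lambda_i + \lambda_j} /
#'   [(e^{\lambda_i} + e^{\lambda_j + \delta})
#'    (e^{\lambda_i + \delta} + e^{\lambda_j})]}
#' to a tie. At `delta = 0` the standard Bradley-Terry model is recovered
#' and ties have probability zero. All arithmetic is done on the log
#' scale, so qualities far into the tails (|lambda| ~ 50) are safe.
#'
#' @param lambda_i,lambda_j Ward quality parameters (vectorised).
#' @param delta Nonnegative tie parameter.
#' @return A tibble with columns `p_i_beats_j`, `p_j_beats_i`, `p_tie`;
#'   rows sum to one.
#' @examples
#' outcome_probabilities(0, 0, 0.5)  # p_tie = tanh(0.25)
#' @export
outcome_probabilities <- function(lambda_i, lambda_j, delta) {
  check_delta(delta)
  p_ij <- stats::plogis(lambda_i - lambda_j - delta)
  p_ji <- stats::plogis(lambda_j - lambda_i - delta)
  tibble::tibble(
    p_i_beats_j = p_ij,
    p_j_beats_i = p_ji,
    p_tie = exp(log_tie_probability(lambda_i, lambda_j, delta))
  )
}

# log pi(i ties j), vectorised; log(expm1(0)) = -Inf makes delta = 0 give
# probability zero with no special case. Identity used throughout:
# p_tie = (e^{2 delta} - 1) * pi_ij * pi_ji with pi_ij = plogis(li - lj - d).
log_tie_probability <- function(lambda_i, lambda_j, delta) {
  log(expm1(2 * delta)) +
    stats::plogis(lambda_i - lambda_j - delta, log.p = TRUE) +
    stats::plogis(lambda_j - lambda_i - delta, log.p = TRUE)
}

check_delta <- function(delta) {
  if (any(!is.finite(delta)) || any(delta < 0)) {
    stop("tie parameter `delta` must be finite and >= 0", call. = FALSE)
  }
  invisible(delta)
}

#' Log-likelihood of the tied Bradley-Terry model
#'
#' Sums, over unordered ward pairs, the win counts in each direction times
#' the log win probabilities plus the tie count times the log tie
#' probability. Algebraically this equals the ordered-pair product form
#' \eqn{(e^{2\delta}-1)^{\sum t_{ij}/2} \prod \pi_{ij}^{y_{ij}+t_{ij}}}
#' exactly (no constant offset), and it is invariant under adding a
#' constant to every quality.
#'
#' @param data A [comparison_table()].
#' @param lambda Numeric quality vector of length `data$n_wards`.
#' @param delta Nonnegative tie parameter.
#' @return Log-likelihood (scalar). `-Inf` when ties are observed but
#'   `delta = 0`.
#' @export
log_likelihood_ties <- function(data, lambda, delta) {
  data <- as_comparison_table(data)
  check_delta(delta)
  if (length(lambda) != data$n_wards) {
    stop("`lambda` must have length ", data$n_wards, call. = FALSE)
  }
  d <- build_design_matrix(data)
  loglik_from_design(d, lambda, delta)
}

# Ordered-pair form evaluated on a prebuilt design; used by the samplers.
loglik_from_design <- function(design, lambda, delta) {
  t_total <- design$total_ties
  tie_term <- if (t_total > 0) t_total * log(expm1(2 * delta)) else 0
  psi <- lambda[design$pairs$i] - lambda[design$pairs$j] - delta
  tie_term + sum(design$pairs$exposure * stats::plogis(psi, log.p = TRUE))
}

#' Log-likelihood of the standard (no-ties) Bradley-Terry model
#'
#' Binomial likelihood over unordered pairs, with success probability
#' `plogis(lambda_i - lambda_j)` and the binomial coefficient included.
#' Only valid when the table records no tied comparisons.
#'
#' @inheritParams log_likelihood_ties
#' @return Log-likelihood (scalar).
#' @export
log_likelihood_standard <- function(data, lambda) {
  data <- as_comparison_table(data)
  if (any(data$ties != 0L)) {
    stop("standard Bradley-Terry likelihood is undefined with ties; ",
         "use log_likelihood_ties()", call. = FALSE)
  }
  if (length(lambda) != data$n_wards) {
    stop("`lambda` must have length ", data$n_wards, call. = FALSE)
  }
  up <- which(upper.tri(data$wins) & (data$wins + t(data$wins) > 0L),
              arr.ind = TRUE)
  if (nrow(up) == 0) return(0)
  y_ij <- data$wins[up]
  y_ji <- t(data$wins)[up]
  n_ij <- y_ij + y_ji
  eta <- lambda[up[, 1]] - lambda[up[, 2]]
  sum(lchoose(n_ij, y_ij) +
        y_ij * stats::plogis(eta, log.p = TRUE) +
        y_ji * stats::plogis(-eta, log.p = TRUE))
}

#' Design matrix of signed ward indicators
#'
#' One row per ordered pair `(i, j)` with positive exposure
#' `y_ij + t_ij > 0`, holding `+1` in column `i` and `-1` in column `j`,
#' so that row `r` applied to the quality vector gives
#' `lambda_i - lambda_j`. Rows are ordered lexicographically in `(i, j)`.
#' Ties contribute exposure to both orderings of a pair.
#'
#' @param data A [comparison_table()].
#' @return An object of class `bt_design`: a list with the sparse matrix
#'   `X`, a `pairs` tibble (`i`, `j`, `wins`, `ties`, `exposure`,
#'   `kappa = exposure / 2`), `total_ties` (unordered tie count) and
#'   `n_wards`.
#' @export
build_design_matrix <- function(data) {
  data <- as_comparison_table(data)
  exposure <- data$wins + data$ties
  idx <- which(t(exposure) > 0L, arr.ind = TRUE)  # transpose: row-major order
  pairs <- tibble::tibble(
    i = as.integer(idx[, 2]),
    j = as.integer(idx[, 1])
  )
  pairs$wins <- data$wins[cbind(pairs$i, pairs$j)]
  pairs$ties <- data$ties[cbind(pairs$i, pairs$j)]
  pairs$exposure <- pairs$wins + pairs$ties
  pairs$kappa <- pairs$exposure / 2
  r <- nrow(pairs)
  X <- Matrix::sparseMatrix(
    i = rep(seq_len(r), 2L),
    j = c(pairs$i, pairs$j),
    x = rep(c(1, -1), each = r),
    dims = c(r, data$n_wards)
  )
  n <- data$n_wards
  structure(
    list(X = X, pairs = pairs, total_ties = sum(data$ties) / 2,
         n_wards = n, ward_labels = data$ward_labels,
         # linear index of (i, j) into an n x n matrix, used by the dense
         # accumulation of X'ZX and X'v in the Gibbs updates
         lin_idx = pairs$i + (pairs$j - 1L) * n),
    class = "bt_design"
  )
}

#' @export
print.bt_design <- function(x, ...) {
  cat("<bt_design> ", nrow(x$pairs), " ordered pairs x ",
      x$n_wards, " wards\n", sep = "")
  invisible(x)
}
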