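#' Draw a quality vector from its prior
#'
#' One multivariate-normal draw \eqn{\lambda \sim N(\mu, \alpha^2
#' \Sigma_0)}.
#'
#' @param prior A [prior_spec()].
#' @param alpha2 Signal variance; defaults to the prior's fixed value
#'   and must be supplied when the prior infers it.
#' @return Named quality vector.
#' @export
simulate_lambda <- function(prior, alpha2 = prior$alpha2) {
  if (is.na(alpha2)) {
    stop("prior has alpha2 = \"infer\"; supply `alpha2`", call. = FALSE)
  }
  draw <- as.numeric(
    mvtnorm::rmvnorm(1, mean = prior$mean,
                     sigma = alpha2 * prior$base_covariance)
  )
  names(draw) <- prior$ward_labels
  draw
}

#' Simulate comparative-judgement data from the tied model
#'
#' Each comparison picks an unordered ward pair uniformly at random
#' (the study design showed judges uniformly chosen pairs) and draws
#' one of the three outcomes from [outcome_probabilities()]. A
#' `"familiarity"` scheme restricts each comparison to a uniformly
#' chosen block of wards, mimicking judges who only compare areas they
#' know.
#'
#' @param lambda Named quality vector (names become ward labels).
#' @param delta Nonnegative tie parameter; `0` yields no ties.
#' @param n_comparisons Number of comparisons to generate. The
#'   customary design is about ten per ward.
#' @param pair_scheme `"uniform"` (default) or `"familiarity"`.
#' @param blocks For `"familiarity"`: integer vector assigning each ward
#'   to a judge-familiarity block.
#' @return A [comparison_table()]; total wins plus ties equals
#'   `n_comparisons`.
#' @examples
#' set.seed(1)
#' simulate_comparisons(c(A = 1, B = 0, C = -1), delta = 0.5, 30)
#' @export
simulate_comparisons <- function(lambda, delta, n_comparisons,
                                 pair_scheme = c("uniform", "familiarity"),
                                 blocks = NULL) {
  pair_scheme <- match.arg(pair_scheme)
  check_delta(delta)
  n <- length(lambda)
  if (n < 2) stop("need at least two wards", call. = FALSE)
  if (n_comparisons < 1) stop("need at least one comparison", call. = FALSE)
  labels <- names(lambda) %||% paste0("w", seq_len(n))

  pairs <- utils::combn(n, 2)
  if (pair_scheme == "uniform") {
    pick <- sample.int(ncol(pairs), n_comparisons, replace = TRUE)
  } else {
    if (is.null(blocks) || length(blocks) != n) {
      stop("`blocks` must assign each ward to a familiarity block",
           call. = FALSE)
    }
    same <- blocks[pairs[1, ]] == blocks[pairs[2, ]]
    if (!any(same)) stop("no within-block pairs available", call. = FALSE)
    pick <- sample(which(same), n_comparisons, replace = TRUE)
  }
  counts <- tabulate(pick, nbins = ncol(pairs))

  wins <- matrix(0L, n, n)
  ties <- matrix(0L, n, n)
  active <- which(counts > 0)
  ai <- pairs[1, active]
  aj <- pairs[2, active]
  p_win_i <- stats::plogis(lambda[ai] - lambda[aj] - delta)
  p_win_j <- stats::plogis(lambda[aj] - lambda[ai] - delta)
  p_tie <- exp(log_tie_probability(lambda[ai], lambda[aj], delta))
  for (k in seq_along(active)) {
    draw <- stats::rmultinom(1, counts[active[k]],
                             c(p_win_i[k], p_win_j[k], p_tie[k]))
    i <- ai[k]
    j <- aj[k]
    wins[i, j] <- wins[i, j] + draw[1]
    wins[j, i] <- wins[j, i] + draw[2]
    ties[i, j] <- ties[i, j] + draw[3]
    ties[j, i] <- ties[j, i] + draw[3]
  }
  comparison_table(wins, ties, ward_labels = labels)
}

#' Normalised Wishart covariance draw
#'
#' A Wishart(I, df = N) draw symmetrically normalised to unit diagonal,
#' \eqn{D^{-1/2} W D^{-1/2}} — the non-spatial correlated prior used to
#' probe scalability.
#'
#' @param n_wards Dimension (>= 2).
#' @return Unit-diagonal positive-definite correlation-like matrix.
#' @export
wishart_covariance <- function(n_wards) {
  if (n_wards < 2) stop("`n_wards` must be >= 2", call. = FALSE)
  w <- stats::rWishart(1, df = n_wards, Sigma = diag(n_wards))[, , 1]
  d <- 1 / sqrt(diag(w))
  s <- (d * w) * rep(d, each = n_wards)
  (s + t(s)) / 2
}

#' Near-square lattice ward graph
#'
#' A connected stand-in for a real ward adjacency map: wards are laid
#' out row-major on a near-square lattice with `ceiling(sqrt(N))`
#' columns and edges between horizontal and vertical neighbours;
#' trailing cells are simply absent when `N` is not a full rectangle.
#'
#' @param n_wards Number of wards (>= 2).
#' @return A [ward_graph()] with labels `"w01"`, `"w02"`, ...
#' @examples
#' grid_graph(6)  # 2 x 3 lattice, 7 edges
#' @export
grid_graph <- function(n_wards) {
  if (n_wards < 2) stop("`n_wards` must be >= 2", call. = FALSE)
  nc <- ceiling(sqrt(n_wards))
  adj <- matrix(0, n_wards, n_wards)
  for (k in seq_len(n_wards)) {
    right <- k + 1
    if (right <= n_wards && (k %% nc) != 0) {
      adj[k, right] <- adj[right, k] <- 1
    }
    down <- k + nc
    if (down <= n_wards) adj[k, down] <- adj[down, k] <- 1
  }
  labels <- sprintf(paste0("w%0", nchar(n_wards), "d"), seq_len(n_wards))
  ward_graph(adj, ward_labels = labels)
}

#' Expected tie fraction under the model
#'
#' Average of the tie probability over all unordered ward pairs (the
#' population tie rate under uniform pair selection).
#'
#' @param lambda Quality vector.
#' @param delta Nonnegative tie parameter.
#' @return Expected tie fraction in `[0, 1)`.
#' @export
expected_tie_fraction <- function(lambda, delta) {
  pairs <- utils::combn(length(lambda), 2)
  mean(exp(log_tie_probability(lambda[pairs[1, ]], lambda[pairs[2, ]],
                               delta)))
}

#' Calibrate the tie parameter to a target tie fraction
#'
#' Solves, by monotone root finding, for the `delta` at which the
#' expected tie fraction over uniformly chosen pairs equals `target`.
#' With all qualities equal the closed-form inverse is
#' `2 * atanh(target)`.
#'
#' @param target Desired tie fraction, strictly between 0 and 1.
#' @param lambda Quality vector defining the pair population.
#' @return Calibrated `delta` (nonnegative).
#' @examples
#' delta_for_tie_fraction(tanh(0.234), rep(0, 5))  # ~ 0.468
#' @export
delta_for_tie_fraction <- function(target, lambda) {
  if (!is.numeric(target) || target <= 0 || target >= 1) {
    stop("`target` must lie strictly between 0 and 1", call. = FALSE)
  }
  f <- function(d) expected_tie_fraction(lambda, d) - target
  upper <- 1
  while (f(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e6) stop("target tie fraction unreachable", call. = FALSE)
  }
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Generate a complete synthetic comparative-judgement study
#'
#' Builds the study conditions in one call: a ward structure (grid graph
#' with the matrix-exponential prior, or a normalised Wishart
#' covariance), a quality vector drawn from the prior, a tie parameter
#' (given directly or calibrated to a target tie fraction), and a
#' comparison set — about ten comparisons per ward by default, matching
#' the customary comparative-judgement design.
#'
#' @param n_wards Number of wards.
#' @param n_comparisons Number of comparisons (default
#'   `10 * n_wards`).
#' @param delta_true Tie parameter used for simulation; give exactly one
#'   of `delta_true` and `target_tie_fraction`.
#' @param target_tie_fraction Calibrate `delta` so the expected tie rate
#'   over the simulated quality vector hits this fraction.
#' @param covariance_kind `"network"` (grid graph + matrix-exponential
#'   covariance) or `"wishart"`.
#' @param alpha2_true Signal variance used for the quality draw
#'   (default 1).
#' @param seed Optional seed (applied with `set.seed()`).
#' @param ... Extra arguments to [prior_spec()] (e.g. `chi`).
#' @return A list with `comparisons` (a [comparison_table()]), `graph`
#'   (or `NULL`), `prior`, `lambda_true`, `delta_true`, `alpha2_true`.
#' @export
simulate_study <- function(n_wards, n_comparisons = 10 * n_wards,
                           delta_true = NULL, target_tie_fraction = NULL,
                           covariance_kind = c("network", "wishart"),
                           alpha2_true = 1, seed = NULL, ...) {
  covariance_kind <- match.arg(covariance_kind)
  if (is.null(delta_true) == is.null(target_tie_fraction)) {
    stop("give exactly one of `delta_true` and `target_tie_fraction`",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (covariance_kind == "network") {
    graph <- grid_graph(n_wards)
    prior <- prior_spec(graph, ...)
  } else {
    graph <- NULL
    prior <- prior_spec(wishart_covariance(n_wards), ...)
  }
  lambda <- simulate_lambda(prior, alpha2 = alpha2_true)
  if (is.null(delta_true)) {
    delta_true <- delta_for_tie_fraction(target_tie_fraction, lambda)
  }
  comparisons <- simulate_comparisons(lambda, delta_true, n_comparisons)
  list(comparisons = comparisons, graph = graph, prior = prior,
       lambda_true = lambda, delta_true = delta_true,
       alpha2_true = alpha2_true)
}
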