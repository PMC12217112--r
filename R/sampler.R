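#' Sampler configuration
#'
#' @param n_iterations Total MCMC iterations (default 5000).
#' @param burn_in Iterations discarded before summarisation (default 100).
#' @param delta_step Gaussian random-walk proposal standard deviation for
#'   the tie parameter (default 0.1; see [tune_delta_step()]).
#' @param mh_baseline_step Proposal standard deviation for the
#'   random-walk baseline's quality updates (default 0.1).
#' @param translation `"resample"` (default) draws a fresh average
#'   quality from its prior law at each iteration; `"center"` only
#'   removes the current average. Both leave every identified contrast
#'   untouched.
#' @param delta_init,lambda_init,alpha2_init Initial states; `lambda_init`
#'   defaults to the zero vector.
#' @param seed Integer seed applied via `set.seed()` at the start of a
#'   run; `NULL` leaves the RNG stream alone.
#' @param debug If `TRUE`, assert at every iteration that the
#'   identifiability translation left the likelihood unchanged.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_iterations = 5000, burn_in = 100,
                           delta_step = 0.1, mh_baseline_step = 0.1,
                           translation = c("resample", "center"),
                           delta_init = 0.1, lambda_init = NULL,
                           alpha2_init = 1, seed = NULL, debug = FALSE) {
  translation <- match.arg(translation)
  if (n_iterations < 1 || burn_in < 0 || burn_in >= n_iterations) {
    stop("need 0 <= burn_in < n_iterations with n_iterations >= 1",
         call. = FALSE)
  }
  if (delta_step <= 0 || mh_baseline_step <= 0) {
    stop("proposal step sizes must be positive", call. = FALSE)
  }
  structure(
    list(n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in), delta_step = delta_step,
         mh_baseline_step = mh_baseline_step, translation = translation,
         delta_init = delta_init, lambda_init = lambda_init,
         alpha2_init = alpha2_init, seed = seed, debug = isTRUE(debug)),
    class = "sampler_config"
  )
}

#' Refresh the Polya-Gamma latents
#'
#' Draws each pair's latent from its full conditional
#' `PG(y_ij + t_ij, lambda_i - lambda_j - delta)`.
#'
#' @param design A [build_design_matrix()] result.
#' @param lambda Current quality vector.
#' @param delta Current tie parameter.
#' @return A tibble (class `pg_latents`) with columns `i`, `j`,
#'   `exposures`, `tilts`, `values`.
#' @export
gibbs_update_z <- function(design, lambda, delta) {
  tilts <- lambda[design$pairs$i] - lambda[design$pairs$j] - delta
  out <- tibble::tibble(
    i = design$pairs$i, j = design$pairs$j,
    exposures = design$pairs$exposure,
    tilts = tilts,
    values = sample_pg(design$pairs$exposure, tilts)
  )
  class(out) <- c("pg_latents", class(out))
  out
}

# hot-loop version: plain numeric draw, no container
update_z_values <- function(design, lambda, delta) {
  .rpg_cpp(as.integer(design$pairs$exposure),
           lambda[design$pairs$i] - lambda[design$pairs$j] - delta)
}

#' Conjugate update of the quality vector
#'
#' Given the Polya-Gamma latents the qualities are conditionally
#' Gaussian with precision \eqn{P = X^T Z X + \Sigma^{-1}} and mean
#' \eqn{P^{-1}(X^T(\kappa + \delta z) + \Sigma^{-1}\mu)}, where
#' \eqn{\kappa_{ij} = (y_{ij}+t_{ij})/2}. The draw uses the upper
#' Cholesky factor of the precision (no explicit inverse). With no
#' comparisons at all the update is a plain prior draw.
#'
#' @param design A [build_design_matrix()] result.
#' @param z A `pg_latents` tibble from [gibbs_update_z()].
#' @param delta Current tie parameter.
#' @param prior A [prior_spec()].
#' @param alpha2 Signal variance in force (defaults to the prior's fixed
#'   value).
#' @return Quality vector draw.
#' @export
gibbs_update_lambda <- function(design, z, delta, prior,
                                alpha2 = prior$alpha2) {
  if (is.na(alpha2)) {
    stop("prior has alpha2 = \"infer\"; supply `alpha2`", call. = FALSE)
  }
  n <- prior$n_wards
  if (nrow(design$pairs) == 0) {
    return(simulate_lambda(prior, alpha2 = alpha2))
  }
  fc <- lambda_full_conditional(design, z, delta, prior, alpha2 = alpha2)
  draw <- fc$mean + backsolve(fc$chol_precision, stats::rnorm(n))
  names(draw) <- prior$ward_labels
  draw
}

#' Gaussian full-conditional parameters of the quality vector
#'
#' The mean and precision of the conditionally Gaussian quality update
#' (see [gibbs_update_lambda()]), exposed so the conjugacy algebra can
#' be checked against numerical integration.
#'
#' @inheritParams gibbs_update_lambda
#' @return A list with `mean`, `precision` and `chol_precision` (upper
#'   triangular).
#' @export
lambda_full_conditional <- function(design, z, delta, prior,
                                    alpha2 = prior$alpha2) {
  n <- prior$n_wards
  zv <- if (is.list(z)) z$values else z
  omega <- prior$base_precision / alpha2

  # X has one +1/-1 pair per row, so X'ZX = diag(rowSums(S)) - S where
  # S[i, j] sums z over both orderings of pair (i, j); the ordered rows
  # are unique, so plain indexed assignment accumulates correctly.
  s <- numeric(n * n)
  s[design$lin_idx] <- zv
  s <- matrix(s, n, n)
  s <- s + t(s)
  prec <- omega - s
  diag(prec) <- diag(prec) + rowSums(s)

  # X'(kappa + delta z): +(.) at each row's i, -(.) at its j
  u <- numeric(n * n)
  u[design$lin_idx] <- design$pairs$kappa + delta * zv
  u <- matrix(u, n, n)
  lin <- rowSums(u) - colSums(u) + as.numeric(omega %*% prior$mean)

  ru <- tryCatch(
    chol(prec),
    error = function(e) {
      stop("posterior precision X'ZX + Sigma^{-1} is not positive ",
           "definite", call. = FALSE)
    }
  )
  m <- backsolve(ru, backsolve(ru, lin, transpose = TRUE))
  list(mean = m, precision = prec, chol_precision = ru)
}

# log full conditional of delta (observed-data likelihood x Exp(chi) prior),
# as a function of delta with lambda differences precomputed
delta_log_target <- function(delta, diffs, exposure, total_ties, chi) {
  if (delta < 0) return(-Inf)
  tie_term <- if (total_ties > 0) {
    if (delta == 0) return(-Inf)
    total_ties * log(expm1(2 * delta))
  } else 0
  tie_term +
    sum(exposure * stats::plogis(diffs - delta, log.p = TRUE)) -
    chi * delta
}

#' Metropolis-Hastings update of the tie parameter
#'
#' Gaussian random-walk proposal on `delta`; negative proposals carry
#' zero prior density and are rejected outright. The target is the
#' observed-data likelihood (the Polya-Gamma latents are integrated out)
#' times the Exp(`chi`) prior.
#'
#' @param design A [build_design_matrix()] result.
#' @param lambda Current quality vector.
#' @param delta Current tie parameter.
#' @param chi Exponential prior rate.
#' @param step Proposal standard deviation.
#' @return A list with `delta` (new value) and `accepted` (logical).
#' @export
mh_update_delta <- function(design, lambda, delta, chi, step) {
  diffs <- lambda[design$pairs$i] - lambda[design$pairs$j]
  proposal <- delta + step * stats::rnorm(1)
  if (proposal < 0) {
    return(list(delta = delta, accepted = FALSE))
  }
  ratio <- delta_log_target(proposal, diffs, design$pairs$exposure,
                            design$total_ties, chi) -
    delta_log_target(delta, diffs, design$pairs$exposure,
                     design$total_ties, chi)
  if (is.nan(ratio)) ratio <- -Inf
  if (log(stats::runif(1)) < ratio) {
    list(delta = proposal, accepted = TRUE)
  } else {
    list(delta = delta, accepted = FALSE)
  }
}

#' Identifiability translation of the quality vector
#'
#' The likelihood only involves quality differences, so the average
#' quality is identified by the prior alone. Each iteration removes the
#' current average and (by default) adds a fresh draw from the prior law
#' of the average, \eqn{N(1^T\mu/N, 1^T\Sigma 1/N^2)}; with
#' `resample = FALSE` the average is set to its prior mean instead. The
#' likelihood value is unchanged by construction.
#'
#' @param lambda Quality vector.
#' @param prior A [prior_spec()].
#' @param alpha2 Signal variance in force.
#' @param resample Draw a fresh average (default) or centre only.
#' @return Translated quality vector.
#' @export
translate_lambda <- function(lambda, prior, alpha2 = prior$alpha2,
                             resample = TRUE) {
  law <- total_quality_distribution(prior, alpha2 = alpha2)
  level <- if (resample) {
    stats::rnorm(1, law$mean, sqrt(law$variance))
  } else {
    law$mean
  }
  lambda - mean(lambda) + level
}

#' Fit the tied Bradley-Terry model by Polya-Gamma Gibbs sampling
#'
#' Runs the latent-variable MCMC algorithm: per iteration the
#' Polya-Gamma latents, the quality vector (conjugate Gaussian draw),
#' the identifiability translation, the tie parameter
#' (Metropolis-Hastings) and, when inferred, the signal variance
#' (conjugate inverse-gamma draw) are updated in that order. With a
#' fixed `seed` the trace is bit-reproducible.
#'
#' @param data A [comparison_table()] or long-format data frame
#'   (see [as_comparison_table()]).
#' @param prior A [prior_spec()]; its ward set must match the data.
#' @param config A [sampler_config()].
#' @return A `bt_fit` object holding `lambda_samples` (kept iterations by
#'   wards), `delta_samples`, `alpha2_samples` (if inferred),
#'   `accept_rate_delta`, `wall_time` (seconds), the config and ward
#'   labels. Summarise with [tidy()], [glance()] or [autoplot()].
#' @examples
#' sim <- simulate_study(n_wards = 6, n_comparisons = 60, delta_true = 0.5,
#'                       seed = 1)
#' fit <- run_mcmc(sim$comparisons, sim$prior,
#'                 sampler_config(n_iterations = 200, burn_in = 50,
#'                                seed = 2))
#' glance(fit)
#' @export
run_mcmc <- function(data, prior, config = sampler_config()) {
  data <- as_comparison_table(data)
  check_fit_inputs(data, prior)
  if (!is.null(config$seed)) set.seed(config$seed)
  design <- build_design_matrix(data)
  n <- prior$n_wards
  kept <- config$n_iterations - config$burn_in

  lambda <- config$lambda_init %||% rep(0, n)
  delta <- config$delta_init
  alpha2 <- if (prior$infer_alpha2) config$alpha2_init else prior$alpha2

  lambda_samples <- matrix(NA_real_, kept, n,
                           dimnames = list(NULL, prior$ward_labels))
  delta_samples <- numeric(kept)
  alpha2_samples <- if (prior$infer_alpha2) numeric(kept) else NULL
  n_accept <- 0L

  level_mean <- sum(prior$mean) / n
  level_var0 <- sum(prior$base_covariance) / n^2
  resample <- config$translation == "resample"

  t0 <- proc.time()[["elapsed"]]
  for (it in seq_len(config$n_iterations)) {
    z <- update_z_values(design, lambda, delta)
    lambda <- gibbs_update_lambda(design, z, delta, prior, alpha2 = alpha2)
    if (config$debug) ll_before <- loglik_from_design(design, lambda, delta)
    level <- if (resample) {
      stats::rnorm(1, level_mean, sqrt(alpha2 * level_var0))
    } else {
      level_mean
    }
    lambda <- lambda - mean(lambda) + level
    if (config$debug) {
      ll_after <- loglik_from_design(design, lambda, delta)
      stopifnot(isTRUE(all.equal(ll_before, ll_after, tolerance = 1e-8)))
    }
    step <- mh_update_delta(design, lambda, delta, prior$chi,
                            config$delta_step)
    delta <- step$delta
    if (prior$infer_alpha2) alpha2 <- sample_alpha2(lambda, prior)
    check_state_finite(lambda, delta, alpha2, it)
    if (it > config$burn_in) {
      k <- it - config$burn_in
      lambda_samples[k, ] <- lambda
      delta_samples[k] <- delta
      if (prior$infer_alpha2) alpha2_samples[k] <- alpha2
      n_accept <- n_accept + step$accepted
    }
  }
  wall <- proc.time()[["elapsed"]] - t0

  new_bt_fit(
    lambda_samples = lambda_samples, delta_samples = delta_samples,
    alpha2_samples = alpha2_samples,
    accept_rate_delta = n_accept / kept,
    accept_rate_lambda = NA_real_,
    sampler = "pg", config = config, prior = prior, data = data,
    wall_time = wall
  )
}

#' Fit the tied Bradley-Terry model by random-walk Metropolis
#'
#' Reference sampler targeting the same posterior as [run_mcmc()] with
#' no data augmentation: componentwise Gaussian random-walk updates of
#' each quality parameter against the observed-data likelihood and
#' multivariate-normal prior, the same identifiability translation, the
#' same tie-parameter update, and the conjugate signal-variance draw.
#' It serves as a correctness cross-check and an efficiency comparator;
#' it mixes far more slowly per unit time than the augmented sampler.
#'
#' @inheritParams run_mcmc
#' @return A `bt_fit` object; `accept_rate_lambda` records the average
#'   componentwise acceptance rate.
#' @export
run_mh_baseline <- function(data, prior, config = sampler_config()) {
  data <- as_comparison_table(data)
  check_fit_inputs(data, prior)
  if (!is.null(config$seed)) set.seed(config$seed)
  design <- build_design_matrix(data)
  n <- prior$n_wards
  kept <- config$n_iterations - config$burn_in

  lambda <- config$lambda_init %||% rep(0, n)
  names(lambda) <- prior$ward_labels
  delta <- config$delta_init
  alpha2 <- if (prior$infer_alpha2) config$alpha2_init else prior$alpha2

  lambda_samples <- matrix(NA_real_, kept, n,
                           dimnames = list(NULL, prior$ward_labels))
  delta_samples <- numeric(kept)
  alpha2_samples <- if (prior$infer_alpha2) numeric(kept) else NULL
  n_accept_delta <- 0L
  n_accept_lambda <- 0L

  logdet0 <- 2 * sum(log(diag(prior$chol_base)))
  pair_i <- design$pairs$i
  pair_j <- design$pairs$j
  exposure <- design$pairs$exposure
  total_ties <- design$total_ties
  log_prior_fast <- function(lam, a2) {
    centred <- lam - prior$mean
    q <- as.numeric(crossprod(centred, prior$base_precision %*% centred))
    -0.5 * (n * log(2 * pi) + n * log(a2) + logdet0 + q / a2)
  }
  log_post <- function(lam, dl, a2) {
    tie_term <- if (total_ties > 0) total_ties * log(expm1(2 * dl)) else 0
    tie_term +
      sum(exposure * stats::plogis(lam[pair_i] - lam[pair_j] - dl,
                                   log.p = TRUE)) +
      log_prior_fast(lam, a2)
  }
  lp <- log_post(lambda, delta, alpha2)
  level_mean <- sum(prior$mean) / n
  level_var0 <- sum(prior$base_covariance) / n^2
  resample <- config$translation == "resample"

  t0 <- proc.time()[["elapsed"]]
  for (it in seq_len(config$n_iterations)) {
    acc_it <- 0L
    for (k in seq_len(n)) {
      prop <- lambda
      prop[k] <- prop[k] + config$mh_baseline_step * stats::rnorm(1)
      lp_prop <- log_post(prop, delta, alpha2)
      if (log(stats::runif(1)) < lp_prop - lp) {
        lambda <- prop
        lp <- lp_prop
        acc_it <- acc_it + 1L
      }
    }
    level <- if (resample) {
      stats::rnorm(1, level_mean, sqrt(alpha2 * level_var0))
    } else {
      level_mean
    }
    lambda <- lambda - mean(lambda) + level
    lp <- log_post(lambda, delta, alpha2)
    step <- mh_update_delta(design, lambda, delta, prior$chi,
                            config$delta_step)
    if (step$accepted) {
      delta <- step$delta
      lp <- log_post(lambda, delta, alpha2)
    }
    if (prior$infer_alpha2) {
      alpha2 <- sample_alpha2(lambda, prior)
      lp <- log_post(lambda, delta, alpha2)
    }
    check_state_finite(lambda, delta, alpha2, it)
    if (it > config$burn_in) {
      kk <- it - config$burn_in
      lambda_samples[kk, ] <- lambda
      delta_samples[kk] <- delta
      if (prior$infer_alpha2) alpha2_samples[kk] <- alpha2
      n_accept_delta <- n_accept_delta + step$accepted
      n_accept_lambda <- n_accept_lambda + acc_it
    }
  }
  wall <- proc.time()[["elapsed"]] - t0

  new_bt_fit(
    lambda_samples = lambda_samples, delta_samples = delta_samples,
    alpha2_samples = alpha2_samples,
    accept_rate_delta = n_accept_delta / kept,
    accept_rate_lambda = n_accept_lambda / (kept * n),
    sampler = "mh", config = config, prior = prior, data = data,
    wall_time = wall
  )
}

#' Fit a tied Bradley-Terry model
#'
#' Tidy front door over [run_mcmc()] (the Polya-Gamma Gibbs sampler,
#' default) and [run_mh_baseline()]. Accepts long-format comparison
#' records and either a ward graph, a base covariance matrix, or a
#' ready-made [prior_spec()].
#'
#' @param data Long-format data frame (`ward_a`, `ward_b`, `outcome`) or
#'   a [comparison_table()].
#' @param graph A [ward_graph()] covering every ward in the data.
#' @param covariance Alternative to `graph`: a unit-diagonal base
#'   covariance matrix.
#' @param prior Alternative to both: a full [prior_spec()].
#' @param sampler `"pg"` or `"mh"`.
#' @param ... Prior hyperparameters passed to [prior_spec()] (e.g.
#'   `chi`, `alpha2`, `alpha2_shape`, `alpha2_scale`) when `prior` is
#'   not supplied.
#' @param config A [sampler_config()].
#' @return A `bt_fit` object.
#' @export
bt_fit <- function(data, graph = NULL, covariance = NULL, prior = NULL,
                   sampler = c("pg", "mh"), ...,
                   config = sampler_config()) {
  sampler <- match.arg(sampler)
  data <- as_comparison_table(data)
  if (is.null(prior)) {
    src <- graph %||% covariance
    if (is.null(src)) {
      stop("supply one of `graph`, `covariance` or `prior`", call. = FALSE)
    }
    prior <- prior_spec(src, ...)
  }
  fitter <- if (sampler == "pg") run_mcmc else run_mh_baseline
  fitter(data, prior, config)
}

check_fit_inputs <- function(data, prior) {
  if (!inherits(prior, "bt_prior")) {
    stop("`prior` must be a prior_spec()", call. = FALSE)
  }
  missing <- setdiff(data$ward_labels, prior$ward_labels)
  if (length(missing) > 0) {
    stop("ward(s) present in comparisons but absent from the prior/graph: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (data$n_wards != prior$n_wards ||
      !identical(data$ward_labels, prior$ward_labels)) {
    stop("comparison table and prior must cover the same wards in the ",
         "same order", call. = FALSE)
  }
  invisible(TRUE)
}

check_state_finite <- function(lambda, delta, alpha2, iteration) {
  if (any(!is.finite(lambda)) || !is.finite(delta) ||
      (!is.null(alpha2) && !is.finite(alpha2))) {
    stop("non-finite sampler state at iteration ", iteration, call. = FALSE)
  }
  invisible(TRUE)
}

new_bt_fit <- function(lambda_samples, delta_samples, alpha2_samples,
                       accept_rate_delta, accept_rate_lambda, sampler,
                       config, prior, data, wall_time) {
  structure(
    list(lambda_samples = lambda_samples, delta_samples = delta_samples,
         alpha2_samples = alpha2_samples,
         accept_rate_delta = accept_rate_delta,
         accept_rate_lambda = accept_rate_lambda, sampler = sampler,
         config = config, prior = prior, data = data,
         ward_labels = colnames(lambda_samples), wall_time = wall_time),
    class = "bt_fit"
  )
}

#' @export
print.bt_fit <- function(x, ...) {
  cat("<bt_fit> ", switch(x$sampler,
                          pg = "Polya-Gamma Gibbs",
                          mh = "random-walk Metropolis"),
      " sampler\n", sep = "")
  cat("  ", length(x$ward_labels), " wards, ",
      nrow(x$lambda_samples), " kept iterations (",
      x$config$burn_in, " burn-in)\n", sep = "")
  cat("  delta posterior median ",
      signif(stats::median(x$delta_samples), 3),
      ", acceptance rate ", signif(x$accept_rate_delta, 3), "\n", sep = "")
  if (!is.null(x$alpha2_samples)) {
    cat("  alpha2 posterior median ",
        signif(stats::median(x$alpha2_samples), 3), "\n", sep = "")
  }
  invisible(x)
}

#' Pilot-tune the tie-parameter proposal scale
#'
#' Runs short pilot chains, doubling or halving the random-walk step
#' until the tie-parameter acceptance rate lands in the target band
#' (20-40% by default).
#'
#' @param data Comparison data.
#' @param prior A [prior_spec()].
#' @param step Initial step.
#' @param target Acceptance band.
#' @param pilot_iterations Iterations per pilot chain.
#' @param max_rounds Adjustment rounds before giving up.
#' @param seed Seed for the pilots.
#' @return Tuned step size (numeric).
#' @export
tune_delta_step <- function(data, prior, step = 0.1,
                            target = c(0.2, 0.4),
                            pilot_iterations = 500, max_rounds = 8,
                            seed = NULL) {
  for (round in seq_len(max_rounds)) {
    fit <- run_mcmc(data, prior,
                    sampler_config(n_iterations = pilot_iterations,
                                   burn_in = pilot_iterations %/% 5,
                                   delta_step = step, seed = seed))
    acc <- fit$accept_rate_delta
    if (acc >= target[1] && acc <= target[2]) break
    step <- if (acc > target[2]) step * 2 else step / 2
  }
  step
}
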