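k3_prior <- function(...) {
  a <- matrix(1, 3, 3) - diag(3)
  prior_spec(ward_graph(a), ...)
}

test_that("latent update draws PG at the design tilts", {
  tab <- tiny_table()
  d <- build_design_matrix(tab)
  lam <- c(0.5, -0.2, 0.1)
  set.seed(2)
  z <- gibbs_update_z(d, lam, 0.3)
  expect_equal(z$tilts, lam[z$i] - lam[z$j] - 0.3)
  expect_equal(z$exposures, d$pairs$exposure)
  expect_true(all(z$values > 0))

  # reproducible under a fixed seed
  set.seed(2)
  z2 <- gibbs_update_z(d, lam, 0.3)
  expect_identical(z$values, z2$values)

  # at zero tilt the latent mean is exposure / 4
  wins <- matrix(0L, 2, 2)
  wins[1, 2] <- 3L
  d2 <- build_design_matrix(comparison_table(wins))
  set.seed(3)
  draws <- replicate(4e3, gibbs_update_z(d2, c(0, 0), 0)$values)
  expect_lt(abs(mean(draws) - 3 / 4), 4 * sqrt(pg_var(3, 0) / 4e3))
})

test_that("quality full conditional matches 2-D numerical integration", {
  wins <- matrix(0L, 2, 2)
  wins[1, 2] <- 1L
  tab <- comparison_table(wins)
  d <- build_design_matrix(tab)
  pr <- prior_spec(diag(2), alpha2 = 1)

  z <- 0.31
  fc <- lambda_full_conditional(d, z, delta = 0, prior = pr)

  # quadrature oracle: exp(kappa x - z x^2 / 2) * N(0, I) on a grid
  grid <- seq(-8, 8, length.out = 1201)
  h <- grid[2] - grid[1]
  l1 <- matrix(grid, 1201, 1201)
  l2 <- matrix(grid, 1201, 1201, byrow = TRUE)
  x <- l1 - l2
  logw <- 0.5 * x - z * x^2 / 2 - (l1^2 + l2^2) / 2
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  m1 <- sum(w * l1)
  m2 <- sum(w * l2)
  expect_equal(fc$mean, c(m1, m2), tolerance = 1e-6)
  cov_oracle <- matrix(c(sum(w * (l1 - m1)^2), sum(w * (l1 - m1) * (l2 - m2)),
                         sum(w * (l1 - m1) * (l2 - m2)),
                         sum(w * (l2 - m2)^2)), 2, 2)
  expect_equal(solve(fc$precision), cov_oracle, tolerance = 1e-6)

  # sampled draws agree with the analytic mean
  set.seed(6)
  draws <- replicate(4e3, gibbs_update_lambda(d, z, 0, pr))
  expect_lt(max(abs(rowMeans(draws) - fc$mean)),
            4 * sqrt(max(diag(solve(fc$precision))) / 4e3))
})

test_that("posterior precision is prior precision plus a graph Laplacian", {
  tab <- random_table(5, 40, delta = 0.5, seed = 12)
  d <- build_design_matrix(tab)
  pr <- prior_spec(diag(5), alpha2 = 2)
  set.seed(4)
  z <- gibbs_update_z(d, stats::rnorm(5), 0.2)
  fc <- lambda_full_conditional(d, z, 0.2, pr, alpha2 = 2)
  lap <- fc$precision - pr$base_precision / 2
  # weighted Laplacian: symmetric, zero row sums, nonpositive off-diagonal
  expect_equal(lap, t(lap), tolerance = 1e-12)
  expect_equal(as.numeric(lap %*% rep(1, 5)), rep(0, 5), tolerance = 1e-10)
  expect_true(all(lap[upper.tri(lap)] <= 0))
})

test_that("with no comparisons the quality update is a prior draw", {
  tab <- comparison_table(matrix(0L, 3, 3))
  d <- build_design_matrix(tab)
  pr <- k3_prior(alpha2 = 1)
  set.seed(9)
  draws <- t(replicate(5e3, gibbs_update_lambda(d, numeric(0), 0.1, pr)))
  expect_lt(max(abs(colMeans(draws))), 4 / sqrt(5e3))
  expect_lt(max(abs(stats::cov(draws) - pr$base_covariance)), 0.08)
})

test_that("tie-parameter update recovers its exponential prior without data", {
  tab <- comparison_table(matrix(0L, 2, 2))
  d <- build_design_matrix(tab)
  set.seed(77)
  delta <- 0.5
  keep <- numeric(4e3)
  for (it in seq_len(2e4)) {
    delta <- mh_update_delta(d, c(0, 0), delta, chi = 2, step = 1.2)$delta
    if (it > 4e3 && it %% 4 == 0) keep[(it - 4e3) / 4] <- delta
  }
  ks <- suppressWarnings(
    stats::ks.test(keep, stats::pexp, 2)
  )
  expect_gt(ks$p.value, 0.001)
})

test_that("an all-tied dataset pushes the tie parameter upward", {
  ties <- matrix(0L, 2, 2)
  ties[1, 2] <- ties[2, 1] <- 20L
  tab <- comparison_table(matrix(0L, 2, 2), ties)
  d <- build_design_matrix(tab)
  set.seed(55)
  delta <- 0.5
  draws <- numeric(4e3)
  for (it in seq_len(5e3)) {
    delta <- mh_update_delta(d, c(0, 0), delta, chi = 2, step = 0.5)$delta
    if (it > 1e3) draws[it - 1e3] <- delta
  }
  expect_gt(mean(draws), 1 / 2)  # well above the Exp(2) prior mean
})

test_that("negative tie proposals are always rejected", {
  tab <- tiny_table()
  d <- build_design_matrix(tab)
  set.seed(13)
  for (k in 1:200) {
    res <- mh_update_delta(d, stats::rnorm(3), 0.01, chi = 0.01, step = 1)
    expect_gte(res$delta, 0)
  }
})

test_that("translation preserves the likelihood and the average law", {
  tab <- random_table(4, 30, delta = 0.4, seed = 18)
  d <- build_design_matrix(tab)
  pr <- prior_spec(diag(4), alpha2 = 1, mean = rep(0.7, 4))
  lam <- stats::rnorm(4)

  set.seed(19)
  moved <- translate_lambda(lam, pr)
  expect_equal(loglik_ref <- log_likelihood_ties(tab, lam, 0.4),
               log_likelihood_ties(tab, moved, 0.4), tolerance = 1e-10)

  centred <- translate_lambda(lam, pr, resample = FALSE)
  expect_equal(mean(centred), 0.7, tolerance = 1e-12)

  # long-run mean of the resampled average matches the prior mean
  set.seed(20)
  levels <- replicate(1e4, mean(translate_lambda(lam, pr)))
  law <- total_quality_distribution(pr)
  expect_lt(abs(mean(levels) - law$mean), 4 * sqrt(law$variance / 1e4))
})

test_that("the Gibbs sampler is seed-deterministic and validates config", {
  sim <- simulate_study(n_wards = 5, n_comparisons = 40, delta_true = 0.4,
                        seed = 3)
  f1 <- run_mcmc(sim$comparisons, sim$prior, quick_config(seed = 10))
  f2 <- run_mcmc(sim$comparisons, sim$prior, quick_config(seed = 10))
  expect_identical(f1$lambda_samples, f2$lambda_samples)
  expect_identical(f1$delta_samples, f2$delta_samples)
  expect_identical(f1$alpha2_samples, f2$alpha2_samples)

  expect_error(sampler_config(n_iterations = 100, burn_in = 100),
               "burn_in")
  expect_error(sampler_config(delta_step = 0), "positive")

  # debug mode asserts translation invariance every iteration
  expect_s3_class(
    run_mcmc(sim$comparisons, sim$prior,
             sampler_config(n_iterations = 50, burn_in = 10, seed = 1,
                            debug = TRUE)),
    "bt_fit"
  )
})

test_that("fitting requires a consistent ward set", {
  sim <- simulate_study(n_wards = 4, n_comparisons = 30, delta_true = 0.4,
                        seed = 6)
  small_prior <- prior_spec(diag(3))
  expect_error(run_mcmc(sim$comparisons, small_prior, quick_config()),
               "absent")
  expect_error(bt_fit(as_tibble(sim$comparisons)), "supply one of")
})

test_that("baseline acceptance falls as its step size grows", {
  sim <- simulate_study(n_wards = 4, n_comparisons = 40, delta_true = 0.4,
                        seed = 8)
  cfg <- function(s) sampler_config(n_iterations = 600, burn_in = 100,
                                    seed = 21, mh_baseline_step = s)
  acc <- vapply(c(0.1, 0.8, 3),
                function(s) run_mh_baseline(sim$comparisons, sim$prior,
                                            cfg(s))$accept_rate_lambda,
                numeric(1))
  expect_true(all(diff(acc) < 0))
})

test_that("baseline recovers the prior marginal with no data", {
  tab <- comparison_table(matrix(0L, 3, 3))
  pr <- k3_prior(alpha2 = 1)
  fit <- run_mh_baseline(tab, pr,
                         sampler_config(n_iterations = 2e4, burn_in = 2e3,
                                        seed = 30, mh_baseline_step = 1.5))
  x <- fit$lambda_samples[, 1]
  ess <- ess_ips(x)
  expect_lt(abs(mean(x)), 4 / sqrt(ess))
  expect_lt(abs(stats::var(x) - 1), 0.15)
})

test_that("the tuner lands the tie acceptance in its band", {
  sim <- simulate_study(n_wards = 6, n_comparisons = 80, delta_true = 0.5,
                        seed = 40)
  step <- tune_delta_step(sim$comparisons, sim$prior, step = 5,
                          pilot_iterations = 400, seed = 41)
  fit <- run_mcmc(sim$comparisons, sim$prior,
                  sampler_config(n_iterations = 800, burn_in = 200,
                                 delta_step = step, seed = 42))
  expect_gt(fit$accept_rate_delta, 0.12)
  expect_lt(fit$accept_rate_delta, 0.55)
})
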