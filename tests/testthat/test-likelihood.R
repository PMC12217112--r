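test_that("outcome probabilities match closed forms", {
  # standard model at equal qualities: fair coin, no ties
  p0 <- outcome_probabilities(0, 0, 0)
  expect_equal(p0$p_i_beats_j, 0.5)
  expect_equal(p0$p_j_beats_i, 0.5)
  expect_equal(p0$p_tie, 0)

  # equal qualities, delta = 0.5: p_tie = tanh(delta / 2)
  p1 <- outcome_probabilities(0, 0, 0.5)
  expect_equal(p1$p_tie, tanh(0.25), tolerance = 1e-12)
  expect_equal(p1$p_i_beats_j, (1 - tanh(0.25)) / 2, tolerance = 1e-12)

  # quality lead exactly equal to delta: even odds of the win
  for (lam in c(-3, 0, 2)) {
    for (d in c(0.1, 1)) {
      expect_equal(
        outcome_probabilities(lam + d, lam, d)$p_i_beats_j, 0.5,
        tolerance = 1e-12
      )
    }
  }
})

test_that("the three outcome probabilities always sum to one", {
  set.seed(11)
  for (k in 1:200) {
    li <- stats::runif(1, -50, 50)
    lj <- stats::runif(1, -50, 50)
    d <- stats::rexp(1, 0.5)
    p <- outcome_probabilities(li, lj, d)
    expect_true(all(unlist(p) >= 0 & unlist(p) <= 1))
    expect_equal(p$p_i_beats_j + p$p_j_beats_i + p$p_tie, 1,
                 tolerance = 1e-12)
  }
})

test_that("tie probability grows from 0 towards 1 in delta", {
  deltas <- seq(0, 12, by = 0.5)
  p <- vapply(deltas,
              function(d) outcome_probabilities(0.3, -0.1, d)$p_tie,
              numeric(1))
  expect_equal(p[1], 0)
  expect_true(all(diff(p) > 0))
  expect_gt(p[length(p)], 0.99)
  expect_error(outcome_probabilities(0, 0, -0.1), "delta")
})

test_that("tied log-likelihood matches a brute-force product oracle", {
  wins <- matrix(0L, 2, 2)
  wins[1, 2] <- 2L
  wins[2, 1] <- 1L
  ties <- matrix(0L, 2, 2)
  ties[1, 2] <- ties[2, 1] <- 1L
  tab <- comparison_table(wins, ties)
  lam <- c(0.3, -0.2)
  expect_equal(log_likelihood_ties(tab, lam, 0.4),
               brute_force_loglik(tab, lam, 0.4), tolerance = 1e-12)

  set.seed(21)
  for (k in 1:10) {
    tab <- random_table(4, 25, delta = 0.6)
    lam <- stats::rnorm(4)
    d <- stats::rexp(1)
    expect_equal(log_likelihood_ties(tab, lam, d),
                 brute_force_loglik(tab, lam, d), tolerance = 1e-10)
  }
})

test_that("tied log-likelihood base cases and translation invariance", {
  empty <- comparison_table(matrix(0L, 3, 3))
  expect_equal(log_likelihood_ties(empty, rep(0, 3), 0.5), 0)

  one <- matrix(0L, 2, 2)
  one[1, 2] <- 1L
  expect_equal(log_likelihood_ties(comparison_table(one), c(0, 0), 0),
               log(0.5), tolerance = 1e-12)

  set.seed(5)
  tab <- random_table(5, 40, delta = 0.5)
  lam <- stats::rnorm(5)
  base <- log_likelihood_ties(tab, lam, 0.3)
  for (shift in stats::rnorm(5, sd = 10)) {
    expect_equal(log_likelihood_ties(tab, lam + shift, 0.3), base,
                 tolerance = 1e-9)
  }
  expect_error(log_likelihood_ties(tab, lam[-1], 0.3), "length")
})

test_that("standard likelihood agrees with the tied one at delta = 0", {
  one <- matrix(0L, 2, 2)
  one[1, 2] <- 1L
  expect_equal(log_likelihood_standard(comparison_table(one), c(0, 0)),
               log(0.5), tolerance = 1e-12)
  expect_equal(log_likelihood_standard(comparison_table(matrix(0L, 2, 2)),
                                       c(0, 0)), 0)

  set.seed(31)
  for (k in 1:8) {
    tab <- random_table(4, 30, delta = 0)   # no ties possible
    lam <- stats::rnorm(4)
    # binomial-coefficient constant separates the two forms
    up <- which(upper.tri(tab$wins) & (tab$wins + t(tab$wins) > 0),
                arr.ind = TRUE)
    const <- sum(lchoose(tab$wins[up] + t(tab$wins)[up], tab$wins[up]))
    expect_equal(log_likelihood_standard(tab, lam),
                 log_likelihood_ties(tab, lam, 0) + const,
                 tolerance = 1e-10)
  }
  tab_ties <- tiny_table()
  expect_error(log_likelihood_standard(tab_ties, rep(0, 3)), "ties")
})

test_that("design matrix enumerates ordered pairs with exposure", {
  one <- matrix(0L, 2, 2)
  one[1, 2] <- 1L
  d <- build_design_matrix(comparison_table(one))
  expect_equal(nrow(d$pairs), 1L)
  expect_equal(as.numeric(d$X[1, ]), c(1, -1))

  # a tie contributes exposure to both orderings
  wins <- matrix(0L, 3, 3)
  wins[1, 2] <- 1L
  ties <- matrix(0L, 3, 3)
  ties[1, 3] <- ties[3, 1] <- 1L
  d3 <- build_design_matrix(comparison_table(wins, ties))
  expect_equal(d3$pairs$i, c(1L, 1L, 3L))
  expect_equal(d3$pairs$j, c(2L, 3L, 1L))
  expect_equal(d3$pairs$exposure, c(1L, 1L, 1L))

  # each +1/-1 row annihilates the ones vector
  tab <- random_table(6, 50, delta = 0.4, seed = 9)
  dd <- build_design_matrix(tab)
  expect_equal(as.numeric(dd$X %*% rep(1, 6)), rep(0, nrow(dd$pairs)))
  expect_equal(dd$pairs$kappa, dd$pairs$exposure / 2)
})
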