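path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (k in seq_len(n - 1)) a[k, k + 1] <- a[k + 1, k] <- 1
  ward_graph(a)
}

test_that("network covariance matches closed forms on small graphs", {
  # edgeless graph: exp(0) = I, so the covariance is the identity
  g0 <- suppressWarnings(ward_graph(matrix(0, 3, 3)))
  expect_equal(network_covariance(g0, 1), diag(3), ignore_attr = TRUE)

  # single edge: exp(A) = [[cosh 1, sinh 1], [sinh 1, cosh 1]],
  # normalising gives off-diagonal tanh(1)
  g2 <- ward_graph(matrix(c(0, 1, 1, 0), 2, 2))
  s2 <- network_covariance(g2, 1)
  expect_equal(diag(s2), c(1, 1), ignore_attr = TRUE)
  expect_equal(s2[1, 2], tanh(1), tolerance = 1e-12)

  # alpha2 is a pure scale
  expect_equal(network_covariance(g2, 2), 2 * s2, tolerance = 1e-12)
  expect_error(network_covariance(g2, -1), "positive")
  expect_error(ward_graph(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("network covariance has unit diagonal and is PD on random graphs", {
  set.seed(42)
  for (n in c(5, 16, 64)) {
    a <- matrix(0, n, n)
    edges <- which(upper.tri(a))
    on <- sample(edges, size = max(n, length(edges) %/% 4))
    a[on] <- 1
    a <- pmax(a, t(a))
    g <- suppressWarnings(ward_graph(a))
    s <- network_covariance(g, 1)
    expect_equal(diag(s), rep(1, n), tolerance = 1e-12, ignore_attr = TRUE)
    expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("prior correlation decays with graph distance on a path", {
  g <- path_graph(6)
  s <- network_covariance(g, 1)
  cors <- s[1, 2:6]  # correlation of node 1 with nodes at distance 1..5
  expect_true(all(diff(cors) < 0))
})

test_that("disconnected graphs are allowed with a warning", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 1
  expect_warning(g <- ward_graph(a), "disconnected")
  s <- network_covariance(g, 1)
  expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("prior log density matches the Gaussian formula", {
  g0 <- suppressWarnings(ward_graph(matrix(0, 4, 4)))
  pr <- prior_spec(g0, alpha2 = 1)
  expect_equal(prior_logpdf(rep(0, 4), pr), -2 * log(2 * pi),
               tolerance = 1e-12)

  # independent oracle: hand-written chol-based density on N = 2
  g2 <- ward_graph(matrix(c(0, 1, 1, 0), 2, 2))
  pr2 <- prior_spec(g2, alpha2 = 1.7, mean = c(0.5, -0.5))
  sig <- 1.7 * network_covariance(g2, 1)
  hand <- function(x) {
    r <- chol(sig)
    q <- sum(backsolve(r, x - pr2$mean, transpose = TRUE)^2)
    -0.5 * (2 * log(2 * pi) + 2 * sum(log(diag(r))) + q)
  }
  set.seed(8)
  for (k in 1:5) {
    x <- stats::rnorm(2, sd = 2)
    expect_equal(prior_logpdf(x, pr2), hand(x), tolerance = 1e-10)
  }

  # density falls monotonically along any ray from the mean
  direction <- c(1, -2) / sqrt(5)
  vals <- vapply(seq(0, 4, by = 0.5),
                 function(tt) prior_logpdf(pr2$mean + tt * direction, pr2),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("alpha2 Gibbs draw targets the right inverse-gamma", {
  g0 <- suppressWarnings(ward_graph(matrix(0, 2, 2)))
  pr <- prior_spec(g0, alpha2_shape = 3, alpha2_scale = 2)

  # lambda = (1, 1) with identity base: posterior IG(shape + 1, scale + 1)
  set.seed(14)
  draws <- replicate(4e4, sample_alpha2(c(1, 1), pr))
  shape_post <- 3 + 1
  scale_post <- 2 + 1
  ig_mean <- scale_post / (shape_post - 1)
  ig_sd <- scale_post / ((shape_post - 1) * sqrt(shape_post - 2))
  expect_lt(abs(mean(draws) - ig_mean), 3 * ig_sd / sqrt(4e4))

  # lambda = 0: quadratic form vanishes, prior shape/scale + N/2 only
  set.seed(15)
  d0 <- replicate(4e4, sample_alpha2(c(0, 0), pr))
  m0 <- 2 / (4 - 1)
  s0 <- 2 / ((4 - 1) * sqrt(4 - 2))
  expect_lt(abs(mean(d0) - m0), 3 * s0 / sqrt(4e4))
})

test_that("the average quality has the stated prior law", {
  g0 <- suppressWarnings(ward_graph(matrix(0, 4, 4)))
  pr <- prior_spec(g0, alpha2 = 1)
  law <- total_quality_distribution(pr)
  expect_equal(law$mean, 0)
  expect_equal(law$variance, 0.25)

  pr_m <- prior_spec(g0, alpha2 = 1, mean = rep(1, 4))
  expect_equal(total_quality_distribution(pr_m)$mean, 1)

  g2 <- ward_graph(matrix(c(0, 1, 1, 0), 2, 2))
  pr2 <- prior_spec(g2, alpha2 = 1)
  expect_equal(total_quality_distribution(pr2)$variance,
               (2 + 2 * tanh(1)) / 4, tolerance = 1e-12)
})

test_that("prior spec validates its inputs", {
  expect_error(prior_spec(matrix(c(2, 0, 0, 2), 2, 2)), "unit diagonal")
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # unit diagonal but indefinite
  expect_error(prior_spec(bad), "positive definite")
  g2 <- ward_graph(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(prior_spec(g2, chi = -1), "positive")
  pr_inf <- prior_spec(g2)
  expect_true(pr_inf$infer_alpha2)
  expect_error(prior_logpdf(c(0, 0), pr_inf), "infer")
})
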