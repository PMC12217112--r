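#' Effective sample size (initial positive sequence)
#'
#' Geyer's initial-positive-sequence estimator: sum consecutive pairs of
#' autocorrelations until a pair sum goes nonpositive, giving the
#' integrated autocorrelation time `tau = 2 * sum(Gamma_m) - 1` and
#' `ESS = n / tau`. Constant chains have no meaningful ESS and return
#' `NA` with a warning rather than infinity.
#'
#' @param x Numeric chain (one parameter).
#' @return Estimated effective sample size.
#' @examples
#' set.seed(1)
#' ess_ips(rnorm(1000))  # close to 1000
#' @export
ess_ips <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) return(NA_real_)
  if (stats::var(x) == 0) {
    warning("constant chain: effective sample size undefined",
            call. = FALSE)
    return(NA_real_)
  }
  lag_max <- min(n - 2, 2000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  tau <- -1
  m <- 0
  while (2 * m + 1 <= lag_max) {
    gamma_m <- rho[2 * m + 1] + rho[2 * m + 2]  # rho is 1-indexed at lag 0
    if (is.na(gamma_m) || gamma_m <= 0) break
    tau <- tau + 2 * gamma_m
    m <- m + 1
  }
  tau <- max(tau, 1 / n)
  n / tau
}

#' Effective sample size per second for a fitted model
#'
#' The efficiency measure used to compare samplers: ESS of the tie
#' parameter and the average ESS across all quality parameters, divided
#' by the wall-clock seconds of the run.
#'
#' @param fit A `bt_fit` object (or anything with `delta_samples`,
#'   `lambda_samples` and `wall_time`).
#' @param wall_time Elapsed seconds; defaults to the fit's recorded
#'   wall time.
#' @return A tibble with columns `ess_delta`, `mean_ess_lambda`,
#'   `ess_delta_per_s`, `mean_ess_lambda_per_s`, `wall_time`.
#' @export
ess_per_second <- function(fit, wall_time = fit$wall_time) {
  if (length(fit$delta_samples) == 0) stop("empty trace", call. = FALSE)
  ess_delta <- ess_ips(fit$delta_samples)
  ess_lambda <- apply(fit$lambda_samples, 2, ess_ips)
  tibble::tibble(
    ess_delta = ess_delta,
    mean_ess_lambda = mean(ess_lambda),
    ess_delta_per_s = ess_delta / wall_time,
    mean_ess_lambda_per_s = mean(ess_lambda) / wall_time,
    wall_time = wall_time
  )
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed by splitting one chain into halves;
#' values near 1 indicate the two halves explore the same
#' distribution.
#'
#' @param x Numeric chain.
#' @return R-hat (scalar); `NA` for constant chains.
#' @export
split_rhat <- function(x) {
  x <- as.numeric(x)
  n <- floor(length(x) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  if (stats::var(as.numeric(halves)) == 0) return(NA_real_)
  w <- mean(apply(halves, 2, stats::var))
  b <- n * stats::var(colMeans(halves))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Convergence and efficiency report for a fitted model
#'
#' Per-parameter effective sample sizes and split-chain R-hat for the
#' tie parameter, every ward quality, and (when inferred) the signal
#' variance. Constant chains are flagged.
#'
#' @param fit A `bt_fit` object.
#' @return A tibble with columns `parameter`, `ess`, `ess_per_s`,
#'   `rhat`, `flag`.
#' @export
diagnose <- function(fit) {
  chains <- c(
    list(delta = fit$delta_samples),
    stats::setNames(
      lapply(seq_along(fit$ward_labels),
             function(k) fit$lambda_samples[, k]),
      paste0("lambda_", fit$ward_labels)
    ),
    if (!is.null(fit$alpha2_samples)) list(alpha2 = fit$alpha2_samples)
  )
  ess <- purrr::map_dbl(chains, function(x) {
    suppressWarnings(ess_ips(x))
  })
  tibble::tibble(
    parameter = names(chains),
    ess = ess,
    ess_per_s = ess / fit$wall_time,
    rhat = purrr::map_dbl(chains, split_rhat),
    flag = dplyr::case_when(
      purrr::map_lgl(chains, ~ stats::var(as.numeric(.x)) == 0) ~
        "constant",
      is.na(ess) ~ "undefined",
      TRUE ~ "ok"
    )
  )
}
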