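#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-ward posterior summaries
#'
#' Posterior median, equal-tailed credible interval, variance and mean
#' for each ward quality parameter, ordered from highest estimated
#' prevalence (most negative quality) to lowest.
#'
#' @param x A `bt_fit` object.
#' @param conf_level Credible level for the equal-tailed interval
#'   (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `ward`, `posterior_median`, `ci_lower`,
#'   `ci_upper`, `posterior_variance`, `posterior_mean`.
#' @method tidy bt_fit
#' @export
tidy.bt_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  qs <- apply(x$lambda_samples, 2, stats::quantile,
              probs = c(a, 0.5, 1 - a))
  out <- tibble::tibble(
    ward = x$ward_labels,
    posterior_median = unname(qs[2, ]),
    ci_lower = unname(qs[1, ]),
    ci_upper = unname(qs[3, ]),
    posterior_variance = unname(apply(x$lambda_samples, 2, stats::var)),
    posterior_mean = unname(colMeans(x$lambda_samples))
  )
  dplyr::arrange(out, .data$posterior_median)
}

#' One-row model summary
#'
#' @param x A `bt_fit` object.
#' @param conf_level Credible level for the tie-parameter interval.
#' @param ... Unused.
#' @return A tibble with the sampler, chain sizes, tie-parameter
#'   posterior median and interval, the implied tie probability at equal
#'   qualities `tanh(delta/2)`, signal-variance median (when inferred),
#'   acceptance rate and wall time.
#' @method glance bt_fit
#' @export
glance.bt_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  dq <- stats::quantile(x$delta_samples, c(a, 0.5, 1 - a))
  tibble::tibble(
    sampler = x$sampler,
    n_wards = length(x$ward_labels),
    n_comparisons = n_comparisons(x$data),
    n_kept = length(x$delta_samples),
    delta_median = dq[[2]],
    delta_ci_lower = dq[[1]],
    delta_ci_upper = dq[[3]],
    tie_prob_equal = tanh(dq[[2]] / 2),
    alpha2_median = if (is.null(x$alpha2_samples)) NA_real_ else
      stats::median(x$alpha2_samples),
    accept_rate_delta = x$accept_rate_delta,
    wall_time = x$wall_time
  )
}

#' Plot a fitted tied Bradley-Terry model
#'
#' Three views: `"quality"` (default) shows per-ward posterior medians
#' with credible intervals; `"trace"` shows the tie-parameter trace;
#' `"tie_curve"` shows the probability of a tie against the quality
#' difference at the posterior-median tie parameter.
#'
#' @param object A `bt_fit` object.
#' @param type One of `"quality"`, `"trace"`, `"tie_curve"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bt_fit
#' @export
autoplot.bt_fit <- function(object,
                            type = c("quality", "trace", "tie_curve"),
                            ...) {
  type <- match.arg(type)
  switch(
    type,
    quality = {
      td <- tidy.bt_fit(object)
      td$ward <- factor(td$ward, levels = td$ward)
      ggplot2::ggplot(td, ggplot2::aes(x = .data$posterior_median,
                                       y = .data$ward)) +
        ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                              xmax = .data$ci_upper),
                                 linewidth = 0.3, size = 0.3) +
        ggplot2::labs(
          x = "ward quality (negative = higher prevalence)",
          y = NULL,
          title = "Posterior ward qualities (median, 95% interval)"
        )
    },
    trace = {
      df <- tibble::tibble(iteration = seq_along(object$delta_samples),
                           delta = object$delta_samples)
      ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$delta)) +
        ggplot2::geom_line(linewidth = 0.2) +
        ggplot2::labs(x = "kept iteration", y = expression(delta),
                      title = "Tie-parameter trace")
    },
    tie_curve = plot_tie_curve(stats::median(object$delta_samples))
  )
}

#' Tie probability against quality difference
#'
#' The model's probability that a judge declares a tie for a pair of
#' wards whose qualities differ by `d`, at a given tie parameter. At
#' `d = 0` this is `tanh(delta / 2)`.
#'
#' @param delta Tie parameter (e.g. a posterior median).
#' @param max_diff Plot range for the absolute quality difference.
#' @return A ggplot object.
#' @export
plot_tie_curve <- function(delta, max_diff = 5) {
  check_delta(delta)
  diff <- seq(0, max_diff, length.out = 200)
  df <- tibble::tibble(
    diff = diff,
    p_tie = exp(log_tie_probability(diff, 0, delta))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$diff, .data$p_tie)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "quality difference", y = "P(tie)",
                  title = sprintf("Tie probability at delta = %.3g", delta))
}
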