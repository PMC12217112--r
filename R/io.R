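#' Write a posterior trace as CSV
#'
#' Columns: `iteration` (post burn-in index), `delta`, `alpha2` (empty
#' when fixed), then one `lambda_<label>` column per ward.
#'
#' @param fit A `bt_fit` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  df <- as.data.frame(fit$lambda_samples)
  names(df) <- paste0("lambda_", fit$ward_labels)
  df <- cbind(
    iteration = seq_len(nrow(df)),
    delta = fit$delta_samples,
    alpha2 = fit$alpha2_samples %||% NA_real_,
    df
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a posterior trace CSV back into a summarisable object
#'
#' Reconstructs enough of a `bt_fit` (sample matrices, labels) to run
#' [tidy()], [glance()], [diagnose()] and [autoplot()]; sampler
#' configuration and timing are not stored in the trace and come back as
#' `NA`.
#'
#' @param path A CSV written by [write_trace()].
#' @return A `bt_fit` object (with `wall_time = NA`).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("iteration", "delta")
  if (!all(need %in% names(df)) || nrow(df) == 0) {
    stop("not a trace file (or truncated): ", path, call. = FALSE)
  }
  lam_cols <- grep("^lambda_", names(df), value = TRUE)
  if (length(lam_cols) == 0) {
    stop("trace has no lambda_<ward> columns: ", path, call. = FALSE)
  }
  if (anyNA(df[c("delta", lam_cols)])) {
    stop("trace file is truncated or has missing values: ", path,
         call. = FALSE)
  }
  labels <- sub("^lambda_", "", lam_cols)
  lambda <- as.matrix(df[lam_cols])
  colnames(lambda) <- labels
  alpha2 <- if ("alpha2" %in% names(df) && !anyNA(df$alpha2)) {
    df$alpha2
  } else {
    NULL
  }
  new_bt_fit(
    lambda_samples = lambda, delta_samples = df$delta,
    alpha2_samples = alpha2, accept_rate_delta = NA_real_,
    accept_rate_lambda = NA_real_, sampler = "unknown",
    config = NULL, prior = NULL, data = NULL, wall_time = NA_real_
  )
}

#' Write per-ward posterior summaries as CSV
#'
#' Columns `ward,posterior_median,ci_lower,ci_upper,posterior_variance`
#' with equal-tailed 95% intervals.
#'
#' @param fit A `bt_fit` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(fit, path) {
  td <- tidy.bt_fit(fit)
  utils::write.csv(
    td[c("ward", "posterior_median", "ci_lower", "ci_upper",
         "posterior_variance")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record written alongside every fit: input paths, the resolved
#' sampler configuration (including the seed), package version, wall
#' time and acceptance rates — everything needed to reproduce the trace
#' bit-for-bit.
#'
#' @param fit A `bt_fit` object.
#' @param path Output file.
#' @param inputs Named list of input file paths (recorded verbatim).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fit, path, inputs = list()) {
  cfg <- fit$config
  manifest <- list(
    package = "btties",
    version = as.character(utils::packageVersion("btties")),
    sampler = fit$sampler,
    inputs = inputs,
    config = list(
      n_iterations = cfg$n_iterations, burn_in = cfg$burn_in,
      delta_step = cfg$delta_step,
      mh_baseline_step = cfg$mh_baseline_step,
      translation = cfg$translation, delta_init = cfg$delta_init,
      alpha2_init = cfg$alpha2_init, seed = cfg$seed
    ),
    prior = list(
      chi = fit$prior$chi,
      alpha2 = if (fit$prior$infer_alpha2) "infer" else fit$prior$alpha2,
      alpha2_shape = fit$prior$alpha2_shape,
      alpha2_scale = fit$prior$alpha2_scale
    ),
    wall_time = fit$wall_time,
    accept_rate_delta = fit$accept_rate_delta,
    accept_rate_lambda = fit$accept_rate_lambda
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dense covariance matrix from CSV
#'
#' For non-network priors: a square numeric matrix with a header row of
#' ward labels.
#'
#' @param path CSV matrix file.
#' @return Numeric matrix with ward labels as dimnames.
#' @export
read_covariance <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop("covariance CSV must be square: ", path, call. = FALSE)
  }
  rownames(m) <- colnames(m)
  m
}
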