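#' Ward adjacency graph
#'
#' Undirected, unweighted adjacency between wards, from which the
#' spatially correlated prior covariance is built. Disconnected graphs
#' are permitted (the matrix-exponential covariance stays positive
#' definite) but flagged with a warning, since prior correlation across
#' components is then essentially absent.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param ward_labels Ward identifiers; default dimnames or `"w1"...`.
#' @return An object of class `ward_graph`.
#' @export
ward_graph <- function(adjacency, ward_labels = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square", call. = FALSE)
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (!all(adjacency %in% c(0, 1)) || any(diag(adjacency) != 0)) {
    stop("adjacency must be binary with zero diagonal", call. = FALSE)
  }
  if (is.null(ward_labels)) {
    ward_labels <- rownames(adjacency) %||% paste0("w", seq_len(n))
  }
  ward_labels <- as.character(ward_labels)
  if (length(ward_labels) != n || anyDuplicated(ward_labels)) {
    stop("`ward_labels` must be ", n, " unique identifiers", call. = FALSE)
  }
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(ward_labels, ward_labels)
  g <- structure(
    list(n_wards = n, ward_labels = ward_labels, adjacency = adjacency),
    class = "ward_graph"
  )
  if (!graph_is_connected(g)) {
    warning("ward graph is disconnected; prior correlation across ",
            "components will be negligible", call. = FALSE)
  }
  g
}

# breadth-first reachability from node 1
graph_is_connected <- function(graph) {
  n <- graph$n_wards
  if (n == 1) return(TRUE)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nb <- which(rowSums(graph$adjacency[, frontier, drop = FALSE]) > 0)
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  all(seen)
}

#' @export
print.ward_graph <- function(x, ...) {
  cat("<ward_graph> ", x$n_wards, " wards, ",
      sum(x$adjacency) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Read a ward adjacency edge list from CSV
#'
#' @param path CSV with header `ward_a,ward_b`, one undirected edge per
#'   row.
#' @param ward_labels Optional complete ward set (isolated wards would
#'   otherwise be dropped); labels in the file but not in this set are an
#'   error.
#' @return A [ward_graph()].
#' @export
read_adjacency <- function(path, ward_labels = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("ward_a", "ward_b") %in% names(df))) {
    stop("expected columns `ward_a`, `ward_b` in ", path, call. = FALSE)
  }
  labels <- ward_labels %||% sort(unique(c(df$ward_a, df$ward_b)))
  unknown <- setdiff(unique(c(df$ward_a, df$ward_b)), labels)
  if (length(unknown) > 0) {
    stop("ward label(s) in edge list but not in `ward_labels`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(labels)
  a <- matrix(0, n, n, dimnames = list(labels, labels))
  ia <- match(df$ward_a, labels)
  ib <- match(df$ward_b, labels)
  if (any(ia == ib)) stop("self-loop edge in ", path, call. = FALSE)
  a[cbind(ia, ib)] <- 1
  a[cbind(ib, ia)] <- 1
  ward_graph(a, ward_labels = labels)
}

#' Write a ward graph as an edge-list CSV
#' @param graph A [ward_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(graph, path) {
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency > 0,
               arr.ind = TRUE)
  utils::write.csv(
    tibble::tibble(ward_a = graph$ward_labels[idx[, 1]],
                   ward_b = graph$ward_labels[idx[, 2]]),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Matrix-exponential network covariance
#'
#' Builds the prior covariance \eqn{\Sigma = \alpha^2 D^{-1/2} e^A
#' D^{-1/2}} from the ward adjacency matrix `A`, where `D` holds the
#' diagonal of `e^A`. The matrix exponential gives strongly connected
#' ward pairs high prior correlation; the symmetric normalisation makes
#' every diagonal entry exactly `alpha2`, so the signal variance is
#' described by `alpha2` alone (small values = strong effective spatial
#' smoothing relative to the signal).
#'
#' @param graph A [ward_graph()].
#' @param alpha2 Positive signal variance.
#' @return A symmetric positive-definite matrix with diagonal `alpha2`.
#' @examples
#' g <- grid_graph(4)
#' diag(network_covariance(g, alpha2 = 2))  # all 2
#' @export
network_covariance <- function(graph, alpha2 = 1) {
  if (!inherits(graph, "ward_graph")) {
    stop("`graph` must be a ward_graph", call. = FALSE)
  }
  if (!is.numeric(alpha2) || length(alpha2) != 1 || alpha2 <= 0) {
    stop("`alpha2` must be a positive scalar", call. = FALSE)
  }
  ea <- as.matrix(expm::expm(graph$adjacency))
  d <- 1 / sqrt(diag(ea))
  sigma <- alpha2 * (d * ea) * rep(d, each = nrow(ea))
  sigma <- (sigma + t(sigma)) / 2  # enforce exact symmetry
  dimnames(sigma) <- dimnames(graph$adjacency)
  sigma
}

#' Multivariate-normal prior specification for ward qualities
#'
#' Wraps the prior \eqn{\lambda \sim N(\mu, \alpha^2 \Sigma_0)} where
#' `base_covariance` \eqn{\Sigma_0} has unit diagonal (built from a ward
#' graph via [network_covariance()] or supplied directly, e.g. a
#' normalised Wishart draw), together with the inverse-gamma hyperprior
#' on the signal variance `alpha2` and the exponential prior rate `chi`
#' for the tie parameter. Pass a numeric `alpha2` to fix the signal
#' variance, or `"infer"` (default) to give it the conjugate
#' InverseGamma(`alpha2_shape`, `alpha2_scale`) hyperprior.
#'
#' @param x A [ward_graph()] or a unit-diagonal symmetric
#'   positive-definite base covariance matrix.
#' @param mean Prior mean vector (default zero).
#' @param alpha2 `"infer"` or a fixed positive value.
#' @param alpha2_shape,alpha2_scale Inverse-gamma hyperparameters
#'   (default 0.01, 0.01 — vague).
#' @param chi Rate of the Exp(`chi`) prior on the tie parameter
#'   (default 0.01 — vague).
#' @return An object of class `bt_prior`.
#' @export
prior_spec <- function(x, mean = NULL, alpha2 = "infer",
                       alpha2_shape = 0.01, alpha2_scale = 0.01,
                       chi = 0.01) {
  if (inherits(x, "ward_graph")) {
    base <- network_covariance(x, alpha2 = 1)
    labels <- x$ward_labels
  } else {
    base <- as.matrix(x)
    labels <- rownames(base) %||% paste0("w", seq_len(nrow(base)))
  }
  n <- nrow(base)
  if (!isTRUE(all.equal(base, t(base), tolerance = 1e-10))) {
    stop("base covariance must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(base) - 1) > 1e-10)) {
    stop("base covariance must have unit diagonal (alpha2 carries the ",
         "scale)", call. = FALSE)
  }
  if (is.null(mean)) mean <- rep(0, n)
  if (length(mean) != n) stop("`mean` has wrong length", call. = FALSE)
  infer <- identical(alpha2, "infer")
  if (!infer && (!is.numeric(alpha2) || alpha2 <= 0)) {
    stop("`alpha2` must be \"infer\" or a positive value", call. = FALSE)
  }
  if (alpha2_shape <= 0 || alpha2_scale <= 0 || chi <= 0) {
    stop("hyperparameters must be positive", call. = FALSE)
  }
  chol_base <- tryCatch(
    chol(base),
    error = function(e) stop("base covariance is not positive definite",
                             call. = FALSE)
  )
  structure(
    list(
      n_wards = n, ward_labels = labels, mean = as.numeric(mean),
      base_covariance = base, chol_base = chol_base,
      base_precision = chol2inv(chol_base),
      alpha2 = if (infer) NA_real_ else alpha2, infer_alpha2 = infer,
      alpha2_shape = alpha2_shape, alpha2_scale = alpha2_scale, chi = chi
    ),
    class = "bt_prior"
  )
}

#' @export
print.bt_prior <- function(x, ...) {
  cat("<bt_prior> N(mu, alpha2 * Sigma0), ", x$n_wards, " wards; alpha2 ",
      if (x$infer_alpha2) {
        paste0("~ InvGamma(", x$alpha2_shape, ", ", x$alpha2_scale, ")")
      } else {
        paste0("= ", x$alpha2)
      },
      "; delta ~ Exp(", x$chi, ")\n", sep = "")
  invisible(x)
}

#' Prior log-density of a quality vector
#'
#' Multivariate-normal log density, normalising constant included.
#'
#' @param lambda Quality vector.
#' @param prior A [prior_spec()].
#' @param alpha2 Signal variance to use; defaults to the prior's fixed
#'   value and must be given when the prior infers `alpha2`.
#' @return Log density (scalar).
#' @export
prior_logpdf <- function(lambda, prior, alpha2 = prior$alpha2) {
  if (is.na(alpha2)) {
    stop("prior has alpha2 = \"infer\"; supply a value of `alpha2`",
         call. = FALSE)
  }
  mvtnorm::dmvnorm(lambda, mean = prior$mean,
                   sigma = alpha2 * prior$base_covariance, log = TRUE)
}

#' Conjugate update of the signal variance
#'
#' Gibbs draw of `alpha2` from its inverse-gamma full conditional
#' InverseGamma(shape + N/2, scale + q/2) with
#' \eqn{q = (\lambda-\mu)^T \Sigma_0^{-1} (\lambda-\mu)}.
#'
#' @param lambda Current quality vector.
#' @param prior A [prior_spec()].
#' @return One positive draw.
#' @export
sample_alpha2 <- function(lambda, prior) {
  centred <- lambda - prior$mean
  q <- as.numeric(crossprod(centred, prior$base_precision %*% centred))
  shape <- prior$alpha2_shape + prior$n_wards / 2
  scale <- prior$alpha2_scale + q / 2
  scale / stats::rgamma(1, shape = shape)
}

#' Prior distribution of the average quality
#'
#' The likelihood is invariant to translating all qualities, so the
#' average \eqn{\Lambda = \sum_i \lambda_i / N} is identified only by the
#' prior, under which \eqn{\Lambda \sim N(1^T\mu/N,\; 1^T\Sigma 1/N^2)}.
#' Used by the per-iteration identifiability translation.
#'
#' @param prior A [prior_spec()].
#' @param alpha2 Signal variance; defaults to the prior's fixed value.
#' @return A tibble with columns `mean` and `variance`.
#' @export
total_quality_distribution <- function(prior, alpha2 = prior$alpha2) {
  if (is.na(alpha2)) {
    stop("prior has alpha2 = \"infer\"; supply a value of `alpha2`",
         call. = FALSE)
  }
  n <- prior$n_wards
  tibble::tibble(
    mean = sum(prior$mean) / n,
    variance = alpha2 * sum(prior$base_covariance) / n^2
  )
}
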