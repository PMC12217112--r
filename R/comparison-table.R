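#' Build a comparison table from win and tie count matrices
#'
#' The core data container for a comparative judgement study: an `N x N`
#' matrix of ordered win counts (`wins[i, j]` = number of times ward `i` was
#' judged higher than ward `j`) and a symmetric matrix of tie counts.
#' Wards that appear in no comparison are retained; under a correlated
#' prior they are informed by their neighbours.
#'
#' @param wins Square nonnegative integer matrix with zero diagonal.
#' @param ties Square symmetric nonnegative integer matrix with zero
#'   diagonal. Defaults to all zeros (no tied comparisons).
#' @param ward_labels Character vector of unique ward identifiers; defaults
#'   to the dimnames of `wins` or `"w1"..."wN"`.
#' @return An object of class `comparison_table` with fields `n_wards`,
#'   `ward_labels`, `wins` and `ties`.
#' @examples
#' wins <- matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE)
#' comparison_table(wins, ward_labels = c("A", "B"))
#' @export
comparison_table <- function(wins, ties = NULL, ward_labels = NULL) {
  wins <- as.matrix(wins)
  n <- nrow(wins)
  if (ncol(wins) != n) stop("`wins` must be a square matrix", call. = FALSE)
  if (is.null(ties)) ties <- matrix(0L, n, n)
  ties <- as.matrix(ties)
  if (!all(dim(ties) == c(n, n))) {
    stop("`ties` must have the same dimensions as `wins`", call. = FALSE)
  }
  if (is.null(ward_labels)) {
    ward_labels <- rownames(wins) %||% paste0("w", seq_len(n))
  }
  ward_labels <- as.character(ward_labels)
  if (length(ward_labels) != n || anyDuplicated(ward_labels)) {
    stop("`ward_labels` must be ", n, " unique identifiers", call. = FALSE)
  }
  storage.mode(wins) <- "integer"
  storage.mode(ties) <- "integer"
  dimnames(wins) <- dimnames(ties) <- list(ward_labels, ward_labels)
  x <- structure(
    list(n_wards = n, ward_labels = ward_labels, wins = wins, ties = ties),
    class = "comparison_table"
  )
  validate_comparison_table(x)
}

validate_comparison_table <- function(x) {
  if (any(x$wins < 0L) || any(x$ties < 0L)) {
    stop("comparison counts must be nonnegative", call. = FALSE)
  }
  if (any(diag(x$wins) != 0L) || any(diag(x$ties) != 0L)) {
    stop("a ward cannot be compared with itself (nonzero diagonal)",
         call. = FALSE)
  }
  if (!identical(x$ties, t(x$ties))) {
    stop("the tie count matrix must be symmetric", call. = FALSE)
  }
  x
}

#' Aggregate long-format comparison records into a comparison table
#'
#' Long format has one judged pairing per row with columns `ward_a`,
#' `ward_b` and `outcome`, where outcome `"a"` means ward A was judged
#' higher, `"b"` ward B, and `"tie"` that the judge could not separate
#' them. Skipped pairings carry no model information and must not appear.
#'
#' @param x A data frame with columns `ward_a`, `ward_b`, `outcome`.
#' @param ward_labels Optional complete set of ward identifiers, so wards
#'   with no comparisons stay in the model; defaults to the sorted labels
#'   present in the data.
#' @param ... Unused.
#' @return A [comparison_table()].
#' @examples
#' df <- tibble::tibble(
#'   ward_a = c("A", "A", "B"), ward_b = c("B", "B", "A"),
#'   outcome = c("a", "tie", "b")
#' )
#' as_comparison_table(df)
#' @export
as_comparison_table <- function(x, ward_labels = NULL, ...) {
  UseMethod("as_comparison_table")
}

#' @export
as_comparison_table.comparison_table <- function(x, ward_labels = NULL, ...) x

#' @export
as_comparison_table.data.frame <- function(x, ward_labels = NULL, ...) {
  need <- c("ward_a", "ward_b", "outcome")
  if (!all(need %in% names(x))) {
    stop("expected columns `ward_a`, `ward_b`, `outcome`", call. = FALSE)
  }
  if (nrow(x) == 0) stop("no comparison records supplied", call. = FALSE)
  ward_a <- as.character(x$ward_a)
  ward_b <- as.character(x$ward_b)
  outcome <- as.character(x$outcome)

  self <- which(ward_a == ward_b)
  if (length(self) > 0) {
    stop("ward compared with itself on line(s): ",
         paste(utils::head(self, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(!outcome %in% c("a", "b", "tie"))
  if (length(bad) > 0) {
    stop("unknown outcome token(s) ",
         paste(unique(outcome[bad]), collapse = ", "),
         " on line(s): ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  labels <- ward_labels %||% sort(unique(c(ward_a, ward_b)))
  labels <- as.character(labels)
  unknown <- setdiff(unique(c(ward_a, ward_b)), labels)
  if (length(unknown) > 0) {
    stop("ward label(s) not in `ward_labels`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(labels)
  ia <- match(ward_a, labels)
  ib <- match(ward_b, labels)

  wins <- matrix(0L, n, n)
  ties <- matrix(0L, n, n)
  win_a <- outcome == "a"
  win_b <- outcome == "b"
  is_tie <- outcome == "tie"
  add_counts <- function(m, from, to) {
    if (length(from) == 0) return(m)
    tab <- table(factor(from, levels = seq_len(n)),
                 factor(to, levels = seq_len(n)))
    m + matrix(as.integer(tab), n, n)
  }
  wins <- add_counts(wins, ia[win_a], ib[win_a])
  wins <- add_counts(wins, ib[win_b], ia[win_b])
  ties <- add_counts(ties, ia[is_tie], ib[is_tie])
  ties <- add_counts(ties, ib[is_tie], ia[is_tie])

  comparison_table(wins, ties, ward_labels = labels)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table> ", x$n_wards, " wards, ",
      n_comparisons(x), " comparisons (",
      sum(x$ties) / 2L, " ties)\n", sep = "")
  invisible(x)
}

#' Total number of comparisons in a table
#'
#' Sum over unordered pairs of wins in either direction plus ties.
#'
#' @param data A [comparison_table()].
#' @return Integer count.
#' @export
n_comparisons <- function(data) {
  sum(data$wins) + sum(data$ties) / 2L
}

#' Expand a comparison table back to long format
#'
#' Deterministic inverse of [as_comparison_table()] up to row order:
#' each ordered win becomes an `"a"` row and each tie a single `"tie"`
#' row for the lexicographically first ordering of the pair.
#'
#' @param x A [comparison_table()].
#' @param ... Unused.
#' @return A tibble with columns `ward_a`, `ward_b`, `outcome`.
#' @method as_tibble comparison_table
#' @export
as_tibble.comparison_table <- function(x, ...) {
  idx <- which(x$wins > 0L, arr.ind = TRUE)
  wins <- tibble::tibble(
    ward_a = rep(x$ward_labels[idx[, 1]], x$wins[idx]),
    ward_b = rep(x$ward_labels[idx[, 2]], x$wins[idx]),
    outcome = "a"
  )
  tidx <- which(upper.tri(x$ties) & x$ties > 0L, arr.ind = TRUE)
  ties <- tibble::tibble(
    ward_a = rep(x$ward_labels[tidx[, 1]], x$ties[tidx]),
    ward_b = rep(x$ward_labels[tidx[, 2]], x$ties[tidx]),
    outcome = "tie"
  )
  out <- dplyr::bind_rows(wins, ties)
  dplyr::arrange(out, .data$ward_a, .data$ward_b, .data$outcome)
}

#' Read long-format comparisons from CSV
#'
#' @param path CSV file with header `ward_a,ward_b,outcome` and outcome
#'   values in `a`, `b`, `tie`.
#' @param ward_labels Optional complete ward set (see
#'   [as_comparison_table()]).
#' @return A [comparison_table()].
#' @export
read_comparisons <- function(path, ward_labels = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  if (nrow(df) == 0) {
    stop("no comparison records in ", path, call. = FALSE)
  }
  as_comparison_table(df, ward_labels = ward_labels)
}

#' Write a comparison table as long-format CSV
#'
#' @param data A [comparison_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(data, path) {
  utils::write.csv(as_tibble.comparison_table(data), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
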