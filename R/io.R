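# Delimited-text readers and writers for feature matrices, targets, and
# coefficient tables. Comma or tab separation is inferred from the file
# extension (.tsv/.tab/.txt => tab), and a leading non-numeric column is
# treated as sample identifiers.

sniff_sep <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

check_readable <- function(path) {
  if (!file.exists(path)) {
    adalink_stop(sprintf("file not found: %s", path), "adalink_error_io")
  }
  path
}

#' Read a feature matrix from delimited text
#'
#' Expects a header row of feature names; an optional first column of
#' non-numeric sample identifiers becomes the row names.
#'
#' @param path CSV or TSV file.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return A numeric matrix.
#' @export
read_features <- function(path, sep = NULL) {
  check_readable(path)
  df <- read.csv(path, sep = sep %||% sniff_sep(path), check.names = FALSE)
  if (ncol(df) > 1L && !is.numeric(df[[1]])) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    rownames(df) <- rn
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    adalink_stop(sprintf("non-numeric feature columns in %s", path),
                 "adalink_error_io")
  }
  as.matrix(df)
}

#' Read a target vector from delimited text
#'
#' Expects a header and one numeric column, optionally preceded by a
#' column of sample identifiers (kept as names).
#'
#' @inheritParams read_features
#' @return A named numeric vector.
#' @export
read_target <- function(path, sep = NULL) {
  check_readable(path)
  df <- read.csv(path, sep = sep %||% sniff_sep(path), check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  if (!any(num)) {
    adalink_stop(sprintf("no numeric target column in %s", path),
                 "adalink_error_io")
  }
  y <- df[[which(num)[1]]]
  if (!num[1] && is.character(df[[1]])) names(y) <- df[[1]]
  y
}

#' Write and read a coefficient table
#'
#' The table has one row per term (intercept first, then the features)
#' and one column per problem, preceded by a `term` column.
#'
#' @param coefs Matrix as returned by [coef.adalink()]: (p+1) rows named
#'   `"(Intercept)"` plus feature names, one column per problem.
#' @param path Output CSV file.
#' @return `write_coefficients()` returns `path` invisibly;
#'   `read_coefficients()` returns the coefficient matrix.
#' @export
write_coefficients <- function(coefs, path) {
  df <- data.frame(term = rownames(coefs), coefs,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  check_readable(path)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# Generic matrix writer used by the simulate subcommand.
write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
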