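#' Bundle related regression problems
#'
#' Collects q regression problems that share the same p features into one
#' object. In `"multi_task"` mode every problem concerns the same samples,
#' so `x` is a single n-by-p matrix and `y` holds q target vectors of
#' length n (a matrix, data frame, or list). In `"transfer"` mode the
#' problems concern disjoint samples, so `x` is a list of q matrices with
#' identical column counts and `y` a list of matching target vectors.
#'
#' @param x Feature matrix (multi-task) or list of feature matrices
#'   (transfer). Column names, when present, are carried through to
#'   coefficients.
#' @param y Targets: matrix/data frame with one column per problem, or a
#'   list of numeric vectors. Binomial targets must be coded 0/1.
#' @param family `"gaussian"` or `"binomial"`.
#' @param mode `"multi_task"` or `"transfer"`.
#' @param ids Optional character vector of problem labels; defaults to the
#'   names of `y` or `"problem1"`, `"problem2"`, ...
#' @return An object of class `"problem_set"`.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' y <- cbind(a = rnorm(10), b = rnorm(10))
#' ps <- problem_set(x, y, family = "gaussian", mode = "multi_task")
#' ps
#' @export
problem_set <- function(x, y, family = c("gaussian", "binomial"),
                        mode = c("multi_task", "transfer"), ids = NULL) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (mode == "multi_task") {
    if (is.list(x) && !is.data.frame(x)) {
      adalink_stop("multi_task mode expects a single feature matrix",
                   "adalink_error_input")
    }
    x <- as.matrix(x)
    if (is.data.frame(y)) y <- as.matrix(y)
    if (is.matrix(y)) {
      ids <- ids %||% colnames(y) %||% paste0("problem", seq_len(ncol(y)))
      y <- lapply(seq_len(ncol(y)), function(k) as.numeric(y[, k]))
    } else if (is.list(y)) {
      ids <- ids %||% names(y) %||% paste0("problem", seq_along(y))
      y <- lapply(y, as.numeric)
    } else {
      ids <- ids %||% "problem1"
      y <- list(as.numeric(y))
    }
    xs <- rep(list(x), length(y))
  } else {
    if (!is.list(x) || is.data.frame(x)) x <- list(x)
    if (!is.list(y)) y <- list(y)
    ids <- ids %||% names(y) %||% paste0("problem", seq_along(y))
    xs <- lapply(x, as.matrix)
    y <- lapply(y, as.numeric)
  }
  ps <- structure(list(
    mode = mode, family = family, x = xs, y = y,
    ids = as.character(ids),
    feature_names = colnames(xs[[1]]) %||% paste0("V", seq_len(ncol(xs[[1]])))
  ), class = "problem_set")
  validate_problem_set(ps)
}

#' Validate a problem set
#'
#' Checks the structural invariants of a [problem_set()]: at least one
#' problem, no missing values, at least two samples per problem, an equal
#' number of features everywhere, identical feature matrices in multi-task
#' mode, and 0/1 targets for the binomial family. Each violation raises a
#' distinct, classed error.
#'
#' @param ps A `"problem_set"`.
#' @return `ps`, invisibly unchanged, if all invariants hold.
#' @export
validate_problem_set <- function(ps) {
  stopifnot(inherits(ps, "problem_set"))
  q <- length(ps$y)
  if (q < 1L || length(ps$x) != q) {
    adalink_stop("a problem set needs at least one problem, with one target per feature matrix",
                 "adalink_error_input")
  }
  p <- ncol(ps$x[[1]])
  for (k in seq_len(q)) {
    xk <- ps$x[[k]]; yk <- ps$y[[k]]
    if (ncol(xk) != p) {
      adalink_stop(sprintf(
        "problem %s has %d features, expected %d (all problems must share the feature set)",
        ps$ids[k], ncol(xk), p
      ), "adalink_error_dim")
    }
    if (nrow(xk) != length(yk)) {
      adalink_stop(sprintf("problem %s: %d rows but %d target values",
                           ps$ids[k], nrow(xk), length(yk)),
                   "adalink_error_dim")
    }
    if (nrow(xk) < 2L) {
      adalink_stop(sprintf("problem %s has fewer than 2 samples", ps$ids[k]),
                   "adalink_error_dim")
    }
    if (anyNA(xk) || anyNA(yk) || !all(is.finite(xk)) || !all(is.finite(yk))) {
      adalink_stop(sprintf("problem %s contains missing or non-finite values",
                           ps$ids[k]), "adalink_error_missing")
    }
    if (ps$family == "binomial" && !all(yk %in% c(0, 1))) {
      adalink_stop(sprintf("problem %s: binomial targets must be exactly 0 or 1",
                           ps$ids[k]), "adalink_error_target")
    }
  }
  if (ps$mode == "multi_task") {
    for (k in seq_len(q)[-1]) {
      if (!identical(dim(ps$x[[k]]), dim(ps$x[[1]])) ||
          !isTRUE(all(ps$x[[k]] == ps$x[[1]]))) {
        adalink_stop("multi_task mode requires one shared feature matrix across problems",
                     "adalink_error_shared_matrix")
      }
    }
  }
  invisible(ps)
}

#' @export
print.problem_set <- function(x, ...) {
  cat(sprintf("problem_set: %d %s problem(s), %s family, p = %d\n",
              length(x$y), x$mode, x$family, ncol(x$x[[1]])))
  for (k in seq_along(x$y)) {
    cat(sprintf("  %s: n = %d\n", x$ids[k], length(x$y[[k]])))
  }
  invisible(x)
}

# Balanced fold ids for one problem; stratified assignment rotates the
# per-class remainder folds so overall fold sizes still differ by <= 1.
balanced_folds <- function(n, n_folds, strata = NULL) {
  if (is.null(strata)) {
    return(sample(rep_len(seq_len(n_folds), n)))
  }
  out <- integer(n)
  offset <- 0L
  for (cls in sort(unique(strata))) {
    idx <- which(strata == cls)
    ids <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    out[idx] <- sample(ids)
    offset <- (offset + length(idx)) %% n_folds
  }
  out
}

#' Assign cross-validation folds
#'
#' Produces a balanced random partition of each problem's samples into
#' `n_folds` folds (sizes differing by at most one). In multi-task mode a
#' single shared partition is reused by every problem; in transfer mode
#' each problem receives an independent partition whose randomness depends
#' only on the seed, the problem index, and that problem's data, so one
#' problem's folds are unaffected by changes to the other datasets. With
#' `stratify = TRUE` and a binomial family, class proportions are balanced
#' across folds up to integer rounding (a minority class smaller than
#' `n_folds` legally leaves some folds without minority samples).
#'
#' @param ps A validated [problem_set()].
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @param stratify Stratify on the binary target? Defaults to `TRUE` for
#'   the binomial family. In multi-task mode stratification uses the first
#'   problem's target (one shared partition cannot stratify all targets).
#' @return A list with one integer fold vector per problem.
#' @export
assign_folds <- function(ps, n_folds = 10, seed = 1,
                         stratify = ps$family == "binomial") {
  stopifnot(inherits(ps, "problem_set"), n_folds >= 2)
  n_folds <- as.integer(n_folds)
  for (k in seq_along(ps$y)) {
    if (length(ps$y[[k]]) < n_folds) {
      adalink_stop(sprintf("problem %s has %d samples, fewer than n_folds = %d",
                           ps$ids[k], length(ps$y[[k]]), n_folds),
                   "adalink_error_folds")
    }
  }
  if (ps$mode == "multi_task") {
    strata <- if (stratify && ps$family == "binomial") ps$y[[1]] else NULL
    f <- with_seed(seed, balanced_folds(length(ps$y[[1]]), n_folds, strata))
    folds <- rep(list(f), length(ps$y))
  } else {
    folds <- lapply(seq_along(ps$y), function(k) {
      strata <- if (stratify && ps$family == "binomial") ps$y[[k]] else NULL
      with_seed(seed + 1009L * k,
                balanced_folds(length(ps$y[[k]]), n_folds, strata))
    })
  }
  names(folds) <- ps$ids
  folds
}
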