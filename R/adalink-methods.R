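#' @export
print.adalink <- function(x, ...) {
  cat(sprintf("adalink fit: %s, %s family, %d problem(s), p = %d\n",
              gsub("_", "-", x$mode), x$family, x$q, x$p))
  df <- data.frame(
    problem = x$ids, n = x$n,
    lambda1 = signif(x$lambda1, 4), lambda2 = signif(x$lambda2, 4),
    delta_int = x$delta_int, delta_ext = x$delta_ext,
    nonzero = colSums(x$slopes != 0)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summarise a fitted adalink model
#'
#' @param object An `"adalink"` fit.
#' @param ... Unused.
#' @return A data frame with one row per problem: sample size, selected
#'   hyperparameters, stage-one and final nonzero slope counts, and the
#'   cross-validated deviance at the optimum.
#' @export
summary.adalink <- function(object, ...) {
  df <- data.frame(
    problem = object$ids, n = object$n,
    lambda1 = object$lambda1, lambda2 = object$lambda2,
    delta_int = object$delta_int, delta_ext = object$delta_ext,
    nonzero_stage1 = colSums(object$stage1$slopes != 0),
    nonzero = colSums(object$slopes != 0),
    cv_deviance = vapply(object$cv, function(cv) {
      cv$cv_min %||% NA_real_
    }, numeric(1)),
    row.names = NULL
  )
  class(df) <- c("summary.adalink", class(df))
  df
}

#' @export
print.summary.adalink <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  for (col in c("lambda1", "lambda2", "cv_deviance")) y[[col]] <- signif(y[[col]], 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Coefficients of a fitted adalink model
#'
#' @param object An `"adalink"` fit.
#' @param ... Unused.
#' @return A (p + 1) by q matrix: the intercept row `"(Intercept)"`
#'   stacked on the collapsed slopes, one column per problem.
#' @export
coef.adalink <- function(object, ...) {
  m <- rbind(`(Intercept)` = object$intercepts, object$slopes)
  colnames(m) <- object$ids
  m
}

resolve_problem <- function(object, problem) {
  if (is.character(problem)) {
    k <- match(problem, object$ids)
    if (is.na(k)) {
      adalink_stop(sprintf("unknown problem id '%s'", problem),
                   "adalink_error_input")
    }
    return(k)
  }
  k <- as.integer(problem)
  if (k < 1L || k > object$q) {
    adalink_stop(sprintf("problem index %d out of range 1..%d", k, object$q),
                 "adalink_error_input")
  }
  k
}

align_features <- function(object, newx) {
  newx <- as.matrix(newx)
  nm <- colnames(newx)
  if (!is.null(nm) && !identical(nm, object$feature_names) &&
      setequal(nm, object$feature_names) &&
      anyDuplicated(nm) == 0L) {
    newx <- newx[, object$feature_names, drop = FALSE]
  } else if (!is.null(nm) && !setequal(nm, object$feature_names)) {
    missing <- setdiff(object$feature_names, nm)
    extra <- setdiff(nm, object$feature_names)
    adalink_stop(sprintf(
      "feature names do not match the model (missing: %s; extra: %s)",
      paste(missing, collapse = ", ") %||% "none",
      paste(extra, collapse = ", ") %||% "none"
    ), "adalink_error_features")
  }
  if (ncol(newx) != object$p) {
    adalink_stop(sprintf("new data has %d columns, model expects %d",
                         ncol(newx), object$p), "adalink_error_dim")
  }
  newx
}

#' Predict from a fitted adalink model
#'
#' @param object An `"adalink"` fit.
#' @param newx Matrix with p columns. When it has column names they are
#'   matched (and reordered) against the model's feature names.
#' @param problem Problem index or id whose coefficients to use.
#' @param type `"response"` (inverse-link scale) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector with one prediction per row of `newx`.
#' @export
predict.adalink <- function(object, newx, problem = 1,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  k <- resolve_problem(object, problem)
  newx <- align_features(object, newx)
  predict_response(object$intercepts[k], object$slopes[, k], newx,
                   object$family, type = type)
}

#' @export
fitted.adalink <- function(object, problem = 1, ...) {
  object$fitted[[resolve_problem(object, problem)]]
}

#' @export
residuals.adalink <- function(object, problem = 1, ...) {
  k <- resolve_problem(object, problem)
  object$y[[k]] - object$fitted[[k]]
}

#' Serialise a fitted adalink model to JSON
#'
#' Writes everything needed to reproduce predictions exactly
#' (hyperparameters, stage-one and final coefficients, the non-negative
#' decomposition, fold assignment, seed, and grid) as a structured JSON
#' document. Cross-validation surfaces are not serialised.
#'
#' @param object An `"adalink"` fit.
#' @param path Output file.
#' @return `path`, invisibly. `read_adalink()` returns an `"adalink"`
#'   object that predicts identically to the original.
#' @export
write_adalink <- function(object, path) {
  stopifnot(inherits(object, "adalink"))
  doc <- list(
    package = "adalink", format = 1L,
    family = object$family, mode = object$mode, ids = object$ids,
    feature_names = object$feature_names, p = object$p, q = object$q,
    n = object$n, seed = object$seed, n_folds = object$n_folds,
    nlambda = object$nlambda, alpha_init = object$alpha_init,
    stratify = object$stratify,
    grid = object$grid,
    lambda1 = object$lambda1, lambda2 = object$lambda2,
    delta_int = object$delta_int, delta_ext = object$delta_ext,
    intercepts = object$intercepts,
    slopes = lapply(seq_len(object$q), function(k) unname(object$slopes[, k])),
    gamma = lapply(seq_len(object$q), function(k) unname(object$gamma[, k])),
    stage1 = list(intercepts = object$stage1$intercepts,
                  slopes = lapply(seq_len(object$q), function(k) {
                    unname(object$stage1$slopes[, k])
                  })),
    folds = object$folds
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_adalink
#' @export
read_adalink <- function(path) {
  check_readable(path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$package, "adalink")) {
    adalink_stop(sprintf("%s is not an adalink model document", path),
                 "adalink_error_io")
  }
  # columns are written as a list of per-problem vectors; jsonlite
  # simplifies that to a problems-by-terms matrix, hence the transpose
  as_mat <- function(m, nr) {
    if (is.list(m)) return(matrix(unlist(m), nrow = nr))
    t(matrix(as.matrix(m), ncol = nr))
  }
  slopes <- as_mat(doc$slopes, doc$p)
  rownames(slopes) <- doc$feature_names
  colnames(slopes) <- doc$ids
  obj <- list(
    call = NULL, family = doc$family, mode = doc$mode, ids = doc$ids,
    feature_names = doc$feature_names, p = doc$p, q = doc$q, n = doc$n,
    lambda1 = doc$lambda1, lambda2 = doc$lambda2,
    delta_int = doc$delta_int, delta_ext = doc$delta_ext,
    grid = doc$grid,
    stage1 = list(intercepts = doc$stage1$intercepts,
                  slopes = as_mat(doc$stage1$slopes, doc$p)),
    intercepts = doc$intercepts, slopes = slopes,
    gamma = as_mat(doc$gamma, 2L * doc$p),
    cv = NULL, folds = doc$folds, seed = doc$seed,
    n_folds = doc$n_folds, nlambda = doc$nlambda,
    alpha_init = doc$alpha_init, stratify = doc$stratify,
    fitted = NULL, control = NULL
  )
  structure(obj, class = "adalink")
}
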