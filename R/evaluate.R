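#' Hold-out mean squared error
#'
#' @param y Observed targets.
#' @param yhat Predictions.
#' @return Mean of the squared residuals.
#' @export
test_mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  mean((y - yhat)^2)
}

#' Number of nonzero coefficients
#'
#' Exact zero test: the solver returns exact zeros for inactive
#' coordinates.
#'
#' @param slopes Coefficient vector.
#' @return Integer count.
#' @export
sparsity <- function(slopes) {
  sum(slopes != 0)
}

#' Sign precision of selected coefficients
#'
#' The number of nonzero estimated coefficients whose sign matches the
#' true effect, divided by the number of nonzero estimates. Undefined
#' (`NA`) when nothing is selected; a selected feature whose true effect
#' is zero counts as an incorrect sign.
#'
#' @param est Estimated coefficient vector.
#' @param truth True effects, same length.
#' @return A value in [0, 1], or `NA` for an empty model.
#' @export
sign_precision <- function(est, truth) {
  stopifnot(length(est) == length(truth))
  nz <- est != 0
  if (!any(nz)) return(NA_real_)
  mean(sign(est[nz]) == sign(truth[nz]))
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted half — the rank (Mann-Whitney U) formulation.
#'
#' @param y Binary 0/1 labels; both classes must be present.
#' @param scores Numeric scores.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(y, scores) {
  stopifnot(length(y) == length(scores), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    adalink_stop("both classes must be present to compute an AUC",
                 "adalink_error_input")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Simulation study harness
#'
#' For each configuration and replicate, fits the full-grid model and its
#' `delta = {0} x {0}` reduction (an ordinary cross-validated lasso) on
#' identical data and identical folds, and reports per-problem hold-out
#' metrics plus the per-replicate mean over problems (row
#' `problem = "mean"`). The headline comparison is `mse_ratio`, the
#' hold-out mean squared error of the method divided by that of its own
#' lasso reduction, so a value below one means the adaptive sharing of
#' information helps. Sign precision is `NA` for empty models and excluded
#' from means. Replicate r of configuration c runs on seed
#' `seed + r - 1 + 1000 * (c - 1)` for both data generation and folds.
#'
#' @param configs A [sim_config()] or list of them (their `seed` field is
#'   overridden per replicate as described above).
#' @param n_reps Replicates per configuration.
#' @param delta_int,delta_ext Exponent grids for the full model.
#' @param nlambda,n_folds,control Passed to [adalink()].
#' @param seed Base seed.
#' @return A data frame with one row per (configuration, replicate,
#'   problem or `"mean"`) and metric columns `test_mse`, `lasso_mse`,
#'   `mse_ratio`, `nonzero`, `lasso_nonzero`, `sign_precision`,
#'   `lasso_sign_precision` (plus `auc` columns for binomial
#'   configurations).
#' @export
run_study <- function(configs, n_reps = 10,
                      delta_int = seq(0, 1, by = 0.2),
                      delta_ext = seq(0, 1, by = 0.2),
                      nlambda = 100, n_folds = 10, seed = 1,
                      control = adalink_control()) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  out <- list()
  for (ci in seq_along(configs)) {
    base <- configs[[ci]]
    for (r in seq_len(n_reps)) {
      rep_seed <- seed + (r - 1L) + 1000L * (ci - 1L)
      cfg <- base
      cfg$seed <- as.integer(rep_seed)
      sim <- simulate_replicate(cfg)
      fit <- adalink(sim$train, delta_int = delta_int,
                     delta_ext = delta_ext, nlambda = nlambda,
                     n_folds = n_folds, seed = rep_seed, control = control)
      red <- adalink(sim$train, delta_int = 0, delta_ext = 0,
                     nlambda = nlambda, n_folds = n_folds,
                     seed = rep_seed, control = control)
      rows <- lapply(seq_len(cfg$q), function(k) {
        yte <- sim$test$y[[k]]
        xte <- sim$test$x[[k]]
        pred <- predict(fit, xte, problem = k, type = "response")
        pred0 <- predict(red, xte, problem = k, type = "response")
        row <- data.frame(
          config = ci, replicate = r, problem = fit$ids[k],
          test_mse = test_mse(yte, pred),
          lasso_mse = test_mse(yte, pred0),
          nonzero = sparsity(fit$slopes[, k]),
          lasso_nonzero = sparsity(red$slopes[, k]),
          sign_precision = sign_precision(fit$slopes[, k],
                                          sim$effects[, k]),
          lasso_sign_precision = sign_precision(red$slopes[, k],
                                                sim$effects[, k])
        )
        row$mse_ratio <- row$test_mse / row$lasso_mse
        if (cfg$family == "binomial") {
          row$auc <- roc_auc(yte, pred)
          row$lasso_auc <- roc_auc(yte, pred0)
        }
        row
      })
      tab <- do.call(rbind, rows)
      num <- vapply(tab, is.numeric, logical(1)) &
        !(names(tab) %in% c("config", "replicate"))
      mean_row <- tab[1, ]
      mean_row$problem <- "mean"
      for (col in names(tab)[num]) {
        mean_row[[col]] <- mean(tab[[col]], na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- rbind(tab, mean_row)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
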