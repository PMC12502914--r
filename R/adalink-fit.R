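#' Two-stage sparse multi-task / transfer learning estimator
#'
#' Fits every problem in two stages. Stage one tunes and fits a lasso-like
#' elastic net (mixing `alpha_init`, default 0.95) separately per problem,
#' with the penalty chosen once by cross-validation on the full data.
#' Stage two re-estimates each problem with the sign-split weighted
#' non-negative lasso of [signsplit_fit()], whose penalty factors derive
#' from stage-one coefficients via [internal_weights()],
#' [external_weights()] and [penalty_factors()]. The stage-two penalty and
#' the two scaling exponents are tuned per problem by a grid search with
#' F-fold cross-validation on the same fold assignment:
#'
#' * multi-task mode: for each fold, stage one is refit for *every*
#'   problem on the shared retained rows, and weights are computed from
#'   those fold-excluded coefficients;
#' * transfer mode: stage-one coefficients are computed once per full
#'   dataset, and within a fold of problem k only column k is refit on
#'   dataset k minus that fold — the other problems keep their full-data
#'   coefficients.
#'
#' For each exponent pair the stage-two path is rebuilt from the
#' fold-training data and its penalty factors; cross-validation curves are
#' indexed by path position, pooled out-of-fold predictions give one
#' deviance per candidate, and the winning position is re-solved on the
#' full-data path. Setting both exponent grids to `{0}` makes the
#' estimator an ordinary cross-validated lasso; restricting only
#' `delta_ext` to `{0}` gives an internal-only adaptive lasso whose fit
#' for each problem depends on that problem's data alone.
#'
#' @param x A [problem_set()], or the feature input accepted by
#'   `problem_set()` (a matrix in multi-task mode, a list of matrices in
#'   transfer mode).
#' @param y Targets (ignored when `x` is already a problem set).
#' @param family,mode,ids Passed to [problem_set()] when needed.
#' @param delta_int,delta_ext Candidate scaling exponents for the internal
#'   and external weights (default `{0, 0.2, 0.4, 0.6, 0.8, 1}`).
#' @param nlambda Length of the regularisation paths (at most 100).
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed governing the fold assignment (the only source
#'   of randomness).
#' @param alpha_init Stage-one elastic net mixing parameter (default
#'   0.95, lasso-like).
#' @param stratify Stratify binomial folds? See [assign_folds()].
#' @param control Numerical settings, see [adalink_control()].
#' @return An object of class `"adalink"`; see [coef.adalink()],
#'   [predict.adalink()], [summary.adalink()].
#' @examples
#' sim <- simulate_replicate(sim_config(
#'   mode = "multi_task", q = 2, p = 20, n_train = 40, n_test = 50,
#'   pi_theta = 0.2, pi_delta = 0, seed = 7
#' ))
#' fit <- adalink(sim$train, delta_int = c(0, 1), delta_ext = c(0, 1),
#'                nlambda = 30, n_folds = 5, seed = 7)
#' fit
#' @export
adalink <- function(x, y = NULL, family = c("gaussian", "binomial"),
                    mode = c("multi_task", "transfer"),
                    delta_int = seq(0, 1, by = 0.2),
                    delta_ext = seq(0, 1, by = 0.2),
                    nlambda = 100, n_folds = 10, seed = 1,
                    alpha_init = 0.95, stratify = NULL, ids = NULL,
                    control = adalink_control()) {
  cl <- match.call()
  ps <- if (inherits(x, "problem_set")) {
    validate_problem_set(x)
  } else {
    problem_set(x, y, family = match.arg(family), mode = match.arg(mode),
                ids = ids)
  }
  family <- ps$family
  mode <- ps$mode
  if (length(delta_int) < 1L || length(delta_ext) < 1L ||
      any(delta_int < 0) || any(delta_ext < 0)) {
    adalink_stop("exponent grids must be non-empty and non-negative",
                 "adalink_error_grid")
  }
  stratify <- stratify %||% (family == "binomial")
  stopifnot(nlambda >= 1, nlambda <= 100)

  q <- length(ps$y)
  p <- ncol(ps$x[[1]])
  folds <- assign_folds(ps, n_folds = n_folds, seed = seed,
                        stratify = stratify)

  # Stage 1: tune lambda1 once per problem on the full data.
  cv1 <- lapply(seq_len(q), function(k) {
    cv_enet_lambda(ps$x[[k]], ps$y[[k]], family, alpha = alpha_init,
                   foldid = folds[[k]], nlambda = nlambda, control = control)
  })
  lambda1 <- vapply(cv1, function(f) f$lambda, numeric(1))

  stage1 <- lapply(seq_len(q), function(k) {
    enet_fit(ps$x[[k]], ps$y[[k]], family, alpha = alpha_init,
             lambda = lambda1[k], control = control)
  })
  beta1 <- vapply(stage1, function(f) f$slopes, numeric(p))
  beta1 <- matrix(beta1, nrow = p, ncol = q)

  pairs <- expand.grid(delta_int = sort(unique(delta_int)),
                       delta_ext = sort(unique(delta_ext)),
                       KEEP.OUT.ATTRS = FALSE)
  G <- nrow(pairs)

  # Pooled out-of-fold predictions per problem, exponent pair, and path
  # position (positions past a degenerate short path repeat its last fit).
  oof <- lapply(seq_len(q), function(k) {
    array(NA_real_, c(length(ps$y[[k]]), G, nlambda))
  })

  cv_predict <- function(k, fold_train, B_for_k) {
    xk <- ps$x[[k]]
    w_int <- internal_weights(B_for_k[, k])
    w_ext <- external_weights(B_for_k[, -k, drop = FALSE])
    xtr <- xk[fold_train, , drop = FALSE]
    ytr <- ps$y[[k]][fold_train]
    xte <- xk[!fold_train, , drop = FALSE]
    for (g in seq_len(G)) {
      z <- penalty_factors(w_int, w_ext, pairs$delta_int[g],
                           pairs$delta_ext[g])
      sp <- signsplit_path(xtr, ytr, family, z, nlambda = nlambda,
                           control = control)
      idx <- pmin(seq_len(nlambda), length(sp$lambda))
      eta <- sweep(xte %*% sp$beta[, idx, drop = FALSE], 2,
                   sp$a0[idx], "+")
      oof[[k]][!fold_train, g, ] <<- linkinv(eta, family)
    }
  }

  for (i in seq_len(as.integer(n_folds))) {
    if (mode == "multi_task") {
      tr <- folds[[1]] != i
      B_cv <- vapply(seq_len(q), function(k) {
        enet_fit(ps$x[[k]][tr, , drop = FALSE], ps$y[[k]][tr], family,
                 alpha = alpha_init, lambda = lambda1[k],
                 control = control)$slopes
      }, numeric(p))
      B_cv <- matrix(B_cv, nrow = p, ncol = q)
      for (k in seq_len(q)) cv_predict(k, tr, B_cv)
    } else {
      for (k in seq_len(q)) {
        trk <- folds[[k]] != i
        B_k <- beta1
        B_k[, k] <- enet_fit(ps$x[[k]][trk, , drop = FALSE],
                             ps$y[[k]][trk], family, alpha = alpha_init,
                             lambda = lambda1[k], control = control)$slopes
        cv_predict(k, trk, B_k)
      }
    }
  }

  # Selection and final fits per problem.
  lambda2 <- delta_int_sel <- delta_ext_sel <- numeric(q)
  a0 <- numeric(q)
  beta <- matrix(0, p, q)
  gamma <- matrix(0, 2L * p, q)
  cv_tabs <- vector("list", q)
  fitted_vals <- vector("list", q)
  z_final <- matrix(NA_real_, 2L * p, q)

  for (k in seq_len(q)) {
    w_int <- internal_weights(beta1[, k])
    w_ext <- external_weights(beta1[, -k, drop = FALSE])
    metric <- apply(oof[[k]], c(2, 3), function(col) {
      family_deviance(ps$y[[k]], col, family)
    })
    # Full-data path per pair supplies the lambda2 value at each position.
    full_paths <- lapply(seq_len(G), function(g) {
      z <- penalty_factors(w_int, w_ext, pairs$delta_int[g],
                           pairs$delta_ext[g])
      path <- suppressWarnings(
        lambda_path(ps$x[[k]], ps$y[[k]], family, alpha = 1,
                    penalty_factor = z, nlambda = nlambda, nonneg = TRUE,
                    control = control)
      )
      list(z = z, path = path)
    })
    tab <- do.call(rbind, lapply(seq_len(G), function(g) {
      path <- full_paths[[g]]$path
      data.frame(pair = g, position = seq_len(nlambda),
                 lambda2 = path[pmin(seq_len(nlambda), length(path))],
                 delta_int = pairs$delta_int[g],
                 delta_ext = pairs$delta_ext[g],
                 metric = metric[g, ])
    }))
    sel <- select_hyperparameters(tab)
    lambda2[k] <- sel$lambda2
    delta_int_sel[k] <- sel$delta_int
    delta_ext_sel[k] <- sel$delta_ext
    zk <- full_paths[[sel$pair]]$z
    fin <- signsplit_fit(ps$x[[k]], ps$y[[k]], family,
                         lambda = sel$lambda2, z = zk, control = control)
    a0[k] <- fin$intercept
    beta[, k] <- fin$slopes
    gamma[, k] <- fin$gamma
    z_final[, k] <- fin$z
    cv_tabs[[k]] <- list(pairs = pairs, metric = metric,
                         position = sel$position, pair = sel$pair,
                         cv_min = sel$metric,
                         oof = oof[[k]][, sel$pair, sel$position])
    fitted_vals[[k]] <- predict_response(a0[k], beta[, k], ps$x[[k]],
                                         family, type = "response")
  }

  rownames(beta) <- ps$feature_names
  colnames(beta) <- ps$ids
  structure(list(
    call = cl, family = family, mode = mode, ids = ps$ids,
    feature_names = ps$feature_names, p = p, q = q,
    n = vapply(ps$y, length, integer(1)),
    lambda1 = lambda1, lambda2 = lambda2,
    delta_int = delta_int_sel, delta_ext = delta_ext_sel,
    grid = list(delta_int = sort(unique(delta_int)),
                delta_ext = sort(unique(delta_ext))),
    stage1 = list(intercepts = vapply(stage1, `[[`, numeric(1), "intercept"),
                  slopes = beta1),
    intercepts = a0, slopes = beta, gamma = gamma,
    penalty_factors = z_final,
    cv = cv_tabs, stage1_cv = cv1,
    y = ps$y,
    folds = folds, seed = seed, n_folds = as.integer(n_folds),
    nlambda = nlambda, alpha_init = alpha_init, stratify = stratify,
    fitted = fitted_vals, control = control
  ), class = "adalink")
}

#' Select stage-two hyperparameters from a cross-validation table
#'
#' Returns the row minimising the metric. Exact ties are broken toward no
#' transfer first (`delta_ext = 0`), then no adaptation (`delta_int = 0`),
#' then the larger (sparser) penalty.
#'
#' @param table Data frame with columns `lambda2`, `delta_int`,
#'   `delta_ext`, and `metric` (smaller is better); extra columns are
#'   carried through.
#' @return The selected row (one-row data frame, as a list).
#' @export
select_hyperparameters <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1,
            all(c("lambda2", "delta_int", "delta_ext", "metric") %in%
                  names(table)))
  cand <- table[table$metric == min(table$metric), , drop = FALSE]
  ord <- order(cand$delta_ext, cand$delta_int, -cand$lambda2)
  as.list(cand[ord[1], , drop = FALSE])
}
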