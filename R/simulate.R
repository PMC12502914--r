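#' Configuration of the reference data-generating process
#'
#' Describes one simulated study condition: q related regression problems
#' on p features whose rows follow a mean-zero Gaussian with AR(1)
#' correlation `rho^|j-l|`, spike-and-slab effects split into a component
#' shared by all problems (each entry a Bernoulli(`pi_theta`) indicator
#' times a standard normal) and a problem-specific component
#' (Bernoulli(`pi_delta`) times standard normal), and unit-variance
#' Gaussian noise on the targets. In multi-task mode one feature matrix is
#' shared by all targets; in transfer mode each problem draws its own.
#'
#' Defaults follow the reference study design (q = 3, p = 200, rho = 0.5,
#' n = 100 for multi-task, n = 50/100/200 for transfer), except that the
#' packaged default test-set size is 2000 rather than 10000 to keep
#' desk-scale runs light; pass `n_test = 10000` for the full-size
#' hold-out.
#'
#' @param mode `"multi_task"` or `"transfer"`.
#' @param q Number of problems.
#' @param p Number of features.
#' @param n_train Training samples: a single number (multi-task, or
#'   recycled in transfer mode) or one per problem.
#' @param n_test Test samples per problem.
#' @param rho AR(1) feature correlation in [0, 1); one value, or one per
#'   problem in transfer mode.
#' @param pi_theta Probability that a feature carries a shared effect.
#' @param pi_delta Probability that a feature carries a problem-specific
#'   effect.
#' @param family `"gaussian"` (the reference process) or `"binomial"`, an
#'   extension where targets are drawn Bernoulli(logistic(X B)).
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(mode = c("multi_task", "transfer"), q = 3, p = 200,
                       n_train = NULL, n_test = 2000, rho = 0.5,
                       pi_theta, pi_delta,
                       family = c("gaussian", "binomial"), seed = 1) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  n_train <- n_train %||% if (mode == "multi_task") 100 else c(50, 100, 200)
  if (mode == "multi_task" && length(unique(n_train)) != 1L) {
    adalink_stop("multi_task mode uses one shared training sample size",
                 "adalink_error_input")
  }
  n_train <- rep_len(as.integer(n_train), if (mode == "multi_task") 1L else q)
  n_test <- rep_len(as.integer(n_test), if (mode == "multi_task") 1L else q)
  rho <- rep_len(rho, if (mode == "multi_task") 1L else q)
  if (any(rho < 0) || any(rho >= 1) ||
      pi_theta < 0 || pi_theta > 1 || pi_delta < 0 || pi_delta > 1) {
    adalink_stop("rho must lie in [0, 1) and the effect probabilities in [0, 1]",
                 "adalink_error_input")
  }
  if (any(n_train < 2L) || any(n_test < 1L) || q < 1L || p < 1L) {
    adalink_stop("sample sizes and dimensions must be positive",
                 "adalink_error_input")
  }
  structure(list(mode = mode, q = as.integer(q), p = as.integer(p),
                 n_train = n_train, n_test = n_test, rho = rho,
                 pi_theta = pi_theta, pi_delta = pi_delta,
                 family = family, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw spike-and-slab effects with a shared and a specific component
#'
#' The shared vector theta (one draw, reused by every problem) and the
#' specific matrix Delta (independent per problem) both have entries equal
#' to a Bernoulli indicator times an independent standard normal; the
#' effect matrix is `B[, k] = theta + Delta[, k]`. Uses the session random
#' stream (seed it, or call through [simulate_replicate()]).
#'
#' @param p,q Dimensions.
#' @param pi_theta,pi_delta Inclusion probabilities.
#' @return A p by q matrix.
#' @export
simulate_effects <- function(p, q, pi_theta, pi_delta) {
  theta <- rbinom(p, 1, pi_theta) * rnorm(p)
  delta <- matrix(rbinom(p * q, 1, pi_delta) * rnorm(p * q), p, q)
  theta + delta
}

#' Draw AR(1)-correlated Gaussian features
#'
#' Rows are independent mean-zero Gaussian vectors with correlation
#' `rho^|j-l|` between features j and l, generated by the AR(1) recursion
#' `x_1 = e_1`, `x_j = rho * x_{j-1} + sqrt(1 - rho^2) * e_j`, which is
#' exact for this covariance and costs O(np) rather than a p by p
#' Cholesky factorisation. Uses the session random stream.
#'
#' @param n,p Dimensions.
#' @param rho Correlation decay in [0, 1).
#' @return An n by p matrix with unit-variance columns.
#' @export
simulate_features <- function(n, p, rho = 0.5) {
  stopifnot(rho >= 0, rho < 1)
  e <- matrix(rnorm(n * p), n, p)
  if (rho == 0 || p == 1L) return(e)
  x <- e
  s <- sqrt(1 - rho^2)
  for (j in 2:p) x[, j] <- rho * x[, j - 1] + s * e[, j]
  x
}

#' Simulate one replicate of the reference generating process
#'
#' Draws effects, features, and targets according to a [sim_config()] and
#' splits each problem into a training and a test [problem_set()] (first
#' `n_train` rows train, remaining rows test; train and test rows are
#' independent draws). All randomness flows from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_replicate"` with elements `train`,
#'   `test` (both problem sets), `effects` (the true p by q matrix), and
#'   `config`.
#' @export
simulate_replicate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    p <- config$p; q <- config$q
    B <- simulate_effects(p, q, config$pi_theta, config$pi_delta)
    feature_names <- sprintf("feature%03d", seq_len(p))
    ids <- paste0("problem", seq_len(q))
    draw_y <- function(x, b) {
      eta <- drop(x %*% b)
      if (config$family == "gaussian") {
        eta + rnorm(nrow(x))
      } else {
        rbinom(nrow(x), 1, plogis(eta))
      }
    }
    if (config$mode == "multi_task") {
      n <- config$n_train[1]; m <- config$n_test[1]
      x <- simulate_features(n + m, p, config$rho[1])
      colnames(x) <- feature_names
      ytr <- matrix(NA_real_, n, q); yte <- matrix(NA_real_, m, q)
      for (k in seq_len(q)) {
        yk <- draw_y(x, B[, k])
        ytr[, k] <- yk[seq_len(n)]
        yte[, k] <- yk[n + seq_len(m)]
      }
      colnames(ytr) <- colnames(yte) <- ids
      train <- problem_set(x[seq_len(n), , drop = FALSE], ytr,
                           family = config$family, mode = "multi_task")
      test <- problem_set(x[n + seq_len(m), , drop = FALSE], yte,
                          family = config$family, mode = "multi_task")
    } else {
      xtr <- xte <- ytr <- yte <- vector("list", q)
      for (k in seq_len(q)) {
        nk <- config$n_train[k]; mk <- config$n_test[k]
        xk <- simulate_features(nk + mk, p, config$rho[k])
        colnames(xk) <- feature_names
        yk <- draw_y(xk, B[, k])
        xtr[[k]] <- xk[seq_len(nk), , drop = FALSE]
        xte[[k]] <- xk[nk + seq_len(mk), , drop = FALSE]
        ytr[[k]] <- yk[seq_len(nk)]
        yte[[k]] <- yk[nk + seq_len(mk)]
      }
      names(ytr) <- names(yte) <- ids
      train <- problem_set(xtr, ytr, family = config$family,
                           mode = "transfer")
      test <- problem_set(xte, yte, family = config$family,
                          mode = "transfer")
    }
    rownames(B) <- feature_names
    colnames(B) <- ids
    structure(list(train = train, test = test, effects = B,
                   config = config), class = "sim_replicate")
  })
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf(
    "sim_replicate: %s, %s, q = %d, p = %d, pi_theta = %g, pi_delta = %g, seed = %d\n",
    x$config$mode, x$config$family, x$config$q, x$config$p,
    x$config$pi_theta, x$config$pi_delta, x$config$seed
  ))
  cat(sprintf("  train n: %s; test n: %s; true nonzero effects: %s\n",
              paste(vapply(x$train$y, length, integer(1)), collapse = "/"),
              paste(vapply(x$test$y, length, integer(1)), collapse = "/"),
              paste(colSums(x$effects != 0), collapse = "/")))
  invisible(x)
}
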