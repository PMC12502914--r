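#' Numerical control parameters for the fitting engine
#'
#' @param thresh Coordinate-descent convergence threshold, relative to the
#'   null deviance on the standardised scale.
#' @param maxit Maximum number of coordinate-descent passes.
#' @param lambda_min_ratio Ratio of the smallest to the largest value on a
#'   regularisation path; `NULL` picks 0.01 when p > n and 1e-4 otherwise.
#' @return A list of class `"adalink_control"`.
#' @export
adalink_control <- function(thresh = 1e-9, maxit = 1e5,
                            lambda_min_ratio = NULL) {
  stopifnot(thresh > 0, maxit >= 1)
  structure(list(thresh = thresh, maxit = as.integer(maxit),
                 lambda_min_ratio = lambda_min_ratio),
            class = "adalink_control")
}

# Centre columns and scale them to unit (population) standard deviation.
# Constant columns are flagged: they cannot carry a penalised coefficient.
standardise <- function(x) {
  x <- as.matrix(x)
  m <- colMeans(x)
  s <- sqrt(colMeans(x^2) - m^2)
  ok <- s > 1e-12
  xs <- sweep(x, 2, m, "-")
  xs[, ok] <- sweep(xs[, ok, drop = FALSE], 2, s[ok], "/")
  xs[, !ok] <- 0
  list(xs = xs, centre = m, scale = ifelse(ok, s, 1), ok = ok)
}

# Smallest penalty zeroing all coefficients, from the gradient of the null
# model on a standardised design: max_j |x_j . (y - ybar)| / (n alpha z_j),
# taking only the positive gradient part for non-negative coordinates.
lambda_max_std <- function(xs, y, alpha, pf, nonneg = FALSE) {
  n <- length(y)
  g <- drop(crossprod(xs, y - mean(y))) / n
  score <- if (nonneg) pmax(g, 0) else abs(g)
  fin <- is.finite(pf) & pf > 0
  if (!any(fin)) return(0)
  max(score[fin] / (alpha * pf[fin]))
}

default_ratio <- function(p, n, control) {
  control$lambda_min_ratio %||% if (p > n) 0.01 else 1e-4
}

log_space <- function(from, to, length_out) {
  exp(seq(log(from), log(to), length.out = length_out))
}

#' Build a regularisation path
#'
#' Log-spaced decreasing sequence of penalty values from the smallest value
#' at which every penalised coefficient is zero (computed from the
#' penalty-weighted gradient of the null model on the standardised design)
#' down to a fixed fraction of it (0.01 when p > n, 1e-4 otherwise). With
#' `nonneg = TRUE` the path is for the sign-split problem on the
#' column-augmented design `[X | -X]` and `penalty_factor` must have 2p
#' entries; finite penalty factors are rescaled to average one first.
#'
#' A constant gaussian target has a null gradient everywhere: a
#' single-value degenerate path is returned with a warning. A target
#' merely uncorrelated with every feature still yields a full-length path
#' of tiny values (all fits on it are null).
#'
#' @param x Feature matrix (n by p), unstandardised.
#' @param y Target vector.
#' @param family `"gaussian"` or `"binomial"`.
#' @param alpha Elastic net mixing parameter in (0, 1].
#' @param penalty_factor Positive penalty factors (`Inf` excludes a
#'   coordinate); `NULL` for uniform. Length p, or 2p when `nonneg`.
#' @param nlambda Path length (at most 100 by convention; default 100).
#' @param nonneg Build the path for the sign-split augmented problem?
#' @param control See [adalink_control()].
#' @return Decreasing numeric vector of length `nlambda` (or 1 in the
#'   degenerate case).
#' @export
lambda_path <- function(x, y, family = c("gaussian", "binomial"),
                        alpha = 1, penalty_factor = NULL, nlambda = 100,
                        nonneg = FALSE, control = adalink_control()) {
  family <- match.arg(family)
  stopifnot(alpha > 0, nlambda >= 1)
  x <- as.matrix(x)
  p <- ncol(x)
  st <- standardise(x)
  pf <- penalty_factor %||% rep(1, if (nonneg) 2L * p else p)
  pf <- normalise_pf(pf)
  if (nonneg) {
    stopifnot(length(pf) == 2L * p)
    xs <- cbind(st$xs, -st$xs)
    pf[c(!st$ok, !st$ok)] <- Inf
  } else {
    stopifnot(length(pf) == p)
    xs <- st$xs
    pf[!st$ok] <- Inf
  }
  if (family == "gaussian" && sd(y) == 0) {
    warning("constant gaussian target: degenerate single-value path",
            call. = FALSE)
    return(1e-10)
  }
  lmax <- lambda_max_std(xs, y, alpha, pf, nonneg = nonneg)
  lmax <- max(lmax, 1e-10)
  log_space(lmax, lmax * default_ratio(p, length(y), control), nlambda)
}

# Rescale finite penalty factors to average exactly one; Inf entries are
# hard exclusions. Finite entries must be strictly positive.
normalise_pf <- function(pf) {
  fin <- is.finite(pf)
  if (any(fin)) {
    if (any(pf[fin] <= 0)) {
      adalink_stop("penalty factors must be strictly positive or Inf",
                   "adalink_error_penalty")
    }
    pf[fin] <- pf[fin] / mean(pf[fin])
  }
  pf
}

# glmnet on an already-standardised design with explicit lambdas; the
# wrapper owns standardisation so the optimised objective is exactly
# (1/n) loss + lambda * sum(pf * |coef|) on the standardised scale.
glmnet_std <- function(xs, y, family, alpha, lambda, pf, control,
                       lower = -Inf) {
  # glmnet requires >= 2 columns; pad with an all-zero (inactive) column.
  padded <- ncol(xs) < 2L
  if (padded) {
    xs <- cbind(xs, 0)
    pf <- c(pf, 1)
  }
  fit <- suppressWarnings(glmnet::glmnet(
    xs, y, family = family, alpha = alpha, lambda = lambda,
    standardize = FALSE, intercept = TRUE, penalty.factor = pf,
    lower.limits = lower, thresh = control$thresh, maxit = control$maxit
  ))
  # Positive jerr is a fatal solver error. Negative jerr means the deepest
  # path values did not converge within maxit passes; glmnet returns the
  # converged prefix, which we extend by its last fit so path positions
  # stay aligned.
  if (!is.null(fit$jerr) && fit$jerr > 0) {
    adalink_stop(sprintf(
      "solver error (jerr = %d, npasses = %d, maxit = %d)",
      fit$jerr, fit$npasses, control$maxit
    ), "adalink_error_convergence")
  }
  beta <- as.matrix(fit$beta)
  a0 <- as.numeric(fit$a0)
  if (padded) beta <- beta[-nrow(beta), , drop = FALSE]
  L_req <- length(lambda)
  if (ncol(beta) < 1L) {
    adalink_stop(sprintf("solver returned no fits (jerr = %d)", fit$jerr),
                 "adalink_error_convergence")
  }
  if (ncol(beta) < L_req) {
    pad <- L_req - ncol(beta)
    beta <- cbind(beta, beta[, rep(ncol(beta), pad), drop = FALSE])
    a0 <- c(a0, rep(a0[length(a0)], pad))
  }
  list(a0 = a0, beta = beta, npasses = fit$npasses, lambda = lambda)
}

# Fit a full path on the original scale: returns intercepts (length L) and
# slopes (p x L), both back-transformed from the standardised fit.
path_fit <- function(x, y, family, alpha, lambda, penalty_factor, control) {
  x <- as.matrix(x)
  p <- ncol(x)
  L <- length(lambda)
  pf <- normalise_pf(penalty_factor %||% rep(1, p))
  st <- standardise(x)
  keep <- st$ok & is.finite(pf)
  beta <- matrix(0, p, L)
  if (var(y) == 0) keep[] <- FALSE # constant target: null model only
  if (!any(keep)) {
    return(list(a0 = rep(null_intercept(y, family), L), beta = beta,
                npasses = 0L))
  }
  fit <- glmnet_std(st$xs[, keep, drop = FALSE], y, family, alpha, lambda,
                    pf[keep], control)
  beta[keep, ] <- fit$beta / st$scale[keep]
  a0 <- fit$a0 - drop(crossprod(beta[keep, , drop = FALSE], st$centre[keep]))
  list(a0 = a0, beta = beta, npasses = fit$npasses)
}

# Warm-start sequence descending to a target lambda.
warm_seq <- function(lmax, lambda) {
  lambda <- max(lambda, 1e-12)
  if (lmax <= lambda) return(c(4 * lambda, 2 * lambda, lambda))
  n_steps <- min(100L, max(5L, ceiling(20 * log10(lmax / lambda))))
  log_space(lmax, lambda, n_steps)
}

#' Fit one elastic net model at a fixed penalty
#'
#' Maximises the penalised likelihood with the elastic net penalty
#' `lambda * sum(alpha * |b| + (1 - alpha) * b^2 / 2)` on internally
#' standardised features (the loss is scaled by 1/n, gaussian loss by
#' 1/(2n)); the intercept is unpenalised and coefficients are returned on
#' the original scale. Solved by warm-started coordinate descent along a
#' short path ending at `lambda`. The ridge component follows the
#' coordinate-descent engine's convention of working on a unit-variance
#' gaussian target, so for `alpha < 1` it is effectively scaled by the
#' target's inverse standard deviation; the L1 component is exact in the
#' given units for both families.
#'
#' @inheritParams lambda_path
#' @param lambda Non-negative penalty value.
#' @return A list with `intercept`, `slopes` (length p), `lambda`, and the
#'   coordinate-descent pass count `npasses`.
#' @export
enet_fit <- function(x, y, family = c("gaussian", "binomial"),
                     alpha = 0.95, lambda, penalty_factor = NULL,
                     control = adalink_control()) {
  family <- match.arg(family)
  stopifnot(lambda >= 0)
  x <- as.matrix(x)
  p <- ncol(x)
  pf <- normalise_pf(penalty_factor %||% rep(1, p))
  st <- standardise(x)
  pfx <- pf
  pfx[!st$ok] <- Inf
  lmax <- lambda_max_std(st$xs, y, alpha, pfx)
  fit <- path_fit(x, y, family, alpha, warm_seq(lmax, lambda), pf, control)
  L <- length(fit$a0)
  list(intercept = fit$a0[L], slopes = drop(fit$beta[, L]),
       lambda = lambda, npasses = fit$npasses)
}

#' Cross-validated tuning of the stage-one penalty
#'
#' Builds a regularisation path on the full data, refits it on each
#' training fold, pools the out-of-fold predictions, and returns the path
#' value minimising the pooled deviance (mean squared error for the
#' gaussian family). Ties favour the larger (sparser) penalty.
#'
#' @inheritParams lambda_path
#' @param foldid Integer fold identifiers, one per sample.
#' @return A list with the selected `lambda`, the `path`, and the
#'   cross-validation curve `cvm`.
#' @export
cv_enet_lambda <- function(x, y, family = c("gaussian", "binomial"),
                           alpha = 0.95, foldid, nlambda = 100,
                           control = adalink_control()) {
  family <- match.arg(family)
  x <- as.matrix(x)
  stopifnot(length(foldid) == length(y))
  path <- suppressWarnings(
    lambda_path(x, y, family, alpha = alpha, nlambda = nlambda,
                control = control)
  )
  pred <- matrix(NA_real_, length(y), length(path))
  for (f in sort(unique(foldid))) {
    tr <- foldid != f
    fit <- path_fit(x[tr, , drop = FALSE], y[tr], family, alpha, path,
                    NULL, control)
    eta <- sweep(x[!tr, , drop = FALSE] %*% fit$beta, 2, fit$a0, "+")
    pred[!tr, ] <- linkinv(eta, family)
  }
  cvm <- apply(pred, 2, function(col) family_deviance(y, col, family))
  list(lambda = path[which.min(cvm)], path = path, cvm = cvm)
}

# Sign-split path: non-negative weighted lasso on [X | -X]. z has 2p
# entries (slots 1..p: positive direction, p+1..2p: negative direction);
# Inf entries are dropped before fitting. Returns per-path-position
# intercepts, collapsed original-scale slopes, and the non-negative gamma
# on the standardised scale.
signsplit_path <- function(x, y, family, z, lambda = NULL, nlambda = 100,
                           control = adalink_control()) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(length(z) == 2L * p)
  z <- normalise_pf(z)
  st <- standardise(x)
  z[c(which(!st$ok), p + which(!st$ok))] <- Inf
  keep <- is.finite(z)
  if (is.null(lambda)) {
    aug <- cbind(st$xs, -st$xs)
    lmax <- max(lambda_max_std(aug, y, 1, z, nonneg = TRUE), 1e-10)
    lambda <- log_space(lmax, lmax * default_ratio(p, length(y), control),
                        nlambda)
  }
  L <- length(lambda)
  gamma <- matrix(0, 2L * p, L)
  if (var(y) == 0) keep[] <- FALSE # constant target: null model only
  if (!any(keep)) {
    a0 <- rep(null_intercept(y, family), L)
    return(list(lambda = lambda, a0 = a0, beta = matrix(0, p, L),
                gamma = gamma, z = z, npasses = 0L))
  }
  aug <- cbind(st$xs, -st$xs)[, keep, drop = FALSE]
  fit <- glmnet_std(aug, y, family, alpha = 1, lambda = lambda, z[keep],
                    control, lower = 0)
  gamma[keep, ] <- fit$beta
  beta_std <- gamma[1:p, , drop = FALSE] - gamma[(p + 1):(2 * p), , drop = FALSE]
  beta <- beta_std / st$scale
  a0 <- fit$a0 - drop(crossprod(beta, st$centre))
  list(lambda = lambda, a0 = a0, beta = beta, gamma = gamma, z = z,
       npasses = fit$npasses)
}

#' Sign-split weighted non-negative lasso
#'
#' Decomposes every slope into a positive and a negative part
#' (`beta_j = gamma_j - gamma_{p+j}`, both parts non-negative) and fits the
#' penalised likelihood with the linear penalty
#' `lambda * sum_j z_j * gamma_j` over all 2p parts — equivalently a
#' non-negative weighted lasso on the column-augmented design `[X | -X]`.
#' Finite entries of `z` are rescaled to average one; `Inf` entries exclude
#' a coordinate direction entirely. Features are standardised internally
#' (both directions of a feature share one scale) and slopes are returned
#' on the original scale. Because the two directions of a feature are
#' perfectly collinear, at most one of `gamma_j`, `gamma_{p+j}` is nonzero
#' at the optimum.
#'
#' @inheritParams enet_fit
#' @param z Penalty-factor vector of length 2p with entries in (0, Inf].
#' @return A list with `intercept`, collapsed `slopes` (length p, original
#'   scale), the non-negative `gamma` (length 2p, standardised scale), the
#'   rescaled `z`, `lambda`, and `npasses`.
#' @export
signsplit_fit <- function(x, y, family = c("gaussian", "binomial"),
                          lambda, z, control = adalink_control()) {
  family <- match.arg(family)
  stopifnot(lambda >= 0)
  x <- as.matrix(x)
  p <- ncol(x)
  z <- normalise_pf(z)
  st <- standardise(x)
  zx <- z
  zx[c(which(!st$ok), p + which(!st$ok))] <- Inf
  lmax <- lambda_max_std(cbind(st$xs, -st$xs), y, 1, zx, nonneg = TRUE)
  fit <- signsplit_path(x, y, family, z, lambda = warm_seq(lmax, lambda),
                        control = control)
  L <- length(fit$a0)
  list(intercept = fit$a0[L], slopes = drop(fit$beta[, L]),
       gamma = drop(fit$gamma[, L]), z = fit$z, lambda = lambda,
       npasses = fit$npasses)
}
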