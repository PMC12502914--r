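# Independent convex-optimisation oracles for the penalised fits, built on
# stats::optim (L-BFGS-B) and never on the package's own solver path. Both
# work on the standardised scale the fitting engine declares: columns
# centred and scaled to unit population standard deviation, loss scaled by
# 1/n (gaussian by 1/(2n)), intercept unpenalised.

oracle_standardise <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(x^2) - m^2)
  list(xs = sweep(sweep(x, 2, m, "-"), 2, s, "/"), centre = m, scale = s)
}

oracle_loss <- function(eta, y, family) {
  n <- length(y)
  if (family == "gaussian") {
    sum((y - eta)^2) / (2 * n)
  } else {
    -mean(y * eta - log(1 + exp(eta)))
  }
}

# Objective value of a sign-split fit given ORIGINAL-scale x and the
# non-negative gamma on the standardised scale.
signsplit_objective <- function(x, y, family, lambda, z, intercept, gamma) {
  st <- oracle_standardise(x)
  fin <- is.finite(z)
  zf <- z
  zf[fin] <- z[fin] / mean(z[fin])
  p <- ncol(x)
  beta_std <- gamma[1:p] - gamma[(p + 1):(2 * p)]
  # intercept is reported on the original scale; move to centred coords
  a0_std <- intercept + sum(beta_std * st$centre / st$scale)
  eta <- a0_std + drop(st$xs %*% beta_std)
  oracle_loss(eta, y, family) + lambda * sum(zf[fin] * gamma[fin])
}

# Brute-force solve of the sign-split problem: minimise the penalised
# loss over the non-negative orthant with a free intercept.
oracle_signsplit <- function(x, y, family, lambda, z) {
  st <- oracle_standardise(x)
  p <- ncol(x)
  fin <- is.finite(z)
  zf <- z[fin] / mean(z[fin])
  A <- cbind(st$xs, -st$xs)[, fin, drop = FALSE]
  m <- ncol(A)
  obj <- function(par) {
    eta <- par[1] + drop(A %*% par[-1])
    oracle_loss(eta, y, family) + lambda * sum(zf * par[-1])
  }
  start <- c(if (family == "gaussian") mean(y) else qlogis(mean(pmin(pmax(y, 0.05), 0.95))),
             rep(0.01, m))
  o <- optim(start, obj, method = "L-BFGS-B",
             lower = c(-Inf, rep(0, m)),
             control = list(maxit = 1e5, factr = 10))
  gamma <- numeric(2 * p)
  gamma[fin] <- o$par[-1]
  beta_std <- gamma[1:p] - gamma[(p + 1):(2 * p)]
  slopes <- beta_std / st$scale
  list(intercept = o$par[1] - sum(slopes * st$centre),
       slopes = slopes, gamma = gamma, objective = o$value,
       convergence = o$convergence)
}

# Brute-force elastic net solve via the positive/negative split (exact
# reformulation: at the optimum one part of each pair is zero, so
# u + v = |b| and the ridge term (u - v)^2 = b^2). The ridge component
# follows the glmnet convention: for the gaussian family it is defined on
# the unit-variance target scale, i.e. scaled by 1/sd(y) in original
# units (population sd); the L1 component is scale-exact either way.
oracle_enet <- function(x, y, family, alpha, lambda) {
  st <- oracle_standardise(x)
  p <- ncol(x)
  ridge_scale <- if (family == "gaussian") {
    1 / sqrt(mean((y - mean(y))^2))
  } else {
    1
  }
  obj <- function(par) {
    b <- par[2:(p + 1)] - par[(p + 2):(2 * p + 1)]
    eta <- par[1] + drop(st$xs %*% b)
    pen <- lambda * sum(alpha * (par[-1][1:p] + par[-1][(p + 1):(2 * p)]) +
                          ridge_scale * (1 - alpha) / 2 * b^2)
    oracle_loss(eta, y, family) + pen
  }
  start <- c(if (family == "gaussian") mean(y) else qlogis(mean(pmin(pmax(y, 0.05), 0.95))),
             rep(0.01, 2 * p))
  o <- optim(start, obj, method = "L-BFGS-B",
             lower = c(-Inf, rep(0, 2 * p)),
             control = list(maxit = 1e5, factr = 10))
  b_std <- o$par[2:(p + 1)] - o$par[(p + 2):(2 * p + 1)]
  slopes <- b_std / st$scale
  list(intercept = o$par[1] - sum(slopes * st$centre),
       slopes = slopes, objective = o$value)
}

# KKT / stationarity audit of a sign-split fit on the standardised scale:
# active coordinates must have zero subgradient, inactive ones a
# non-negative one.
kkt_violation <- function(x, y, family, lambda, fit) {
  st <- oracle_standardise(x)
  p <- ncol(x)
  A <- cbind(st$xs, -st$xs)
  z <- fit$z
  eta <- fit$intercept + drop(as.matrix(x) %*% fit$slopes)
  mu <- if (family == "gaussian") eta else plogis(eta)
  grad <- -drop(crossprod(A, y - mu)) / length(y)
  fin <- is.finite(z)
  active <- fin & fit$gamma > 1e-10
  viol_active <- if (any(active)) max(abs(grad[active] + lambda * z[active])) else 0
  inactive <- fin & !active
  viol_inactive <- if (any(inactive)) max(0, -(grad[inactive] + lambda * z[inactive])) else 0
  max(viol_active, viol_inactive)
}

# Exhaustive pairwise AUC: fraction of positive/negative pairs where the
# positive wins, ties counting one half.
auc_bruteforce <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}
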