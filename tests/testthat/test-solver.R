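ctl <- adalink_control(thresh = 1e-12)

test_that("lambda path starts at the analytic null-model bound", {
  set.seed(10)
  n <- 50; p <- 8
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n) + x[, 2]
  for (alpha in c(1, 0.95, 0.5)) {
    path <- lambda_path(x, y, "gaussian", alpha = alpha, nlambda = 40)
    xs <- scale(x, scale = apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))))
    lmax_expected <- max(abs(crossprod(xs, y - mean(y)))) / (n * alpha)
    expect_equal(path[1], lmax_expected, tolerance = 1e-12)
    expect_length(path, 40)
    expect_true(all(diff(path) < 0))
    # at the first path value every penalised coefficient is zero
    fit <- enet_fit(x, y, "gaussian", alpha = alpha, lambda = path[1],
                    control = ctl)
    expect_true(all(abs(fit$slopes) < 1e-8))
  }
  # path ratio convention: 1e-4 for p <= n, 0.01 for p > n
  expect_equal(path[40] / path[1], 1e-4, tolerance = 1e-10)
  xwide <- matrix(rnorm(10 * 20), 10, 20)
  pw <- lambda_path(xwide, rnorm(10), "gaussian", nlambda = 10)
  expect_equal(pw[10] / pw[1], 0.01, tolerance = 1e-10)
})

test_that("penalty-factor rescaling makes the path scale-free and constant targets degenerate", {
  set.seed(11)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  z <- runif(6, 0.5, 2)
  p1 <- lambda_path(x, y, "gaussian", penalty_factor = z)
  p2 <- lambda_path(x, y, "gaussian", penalty_factor = 2 * z)
  expect_equal(p1, p2, tolerance = 1e-12)

  expect_warning(pd <- lambda_path(x, rep(3, 40), "gaussian"),
                 "degenerate")
  expect_length(pd, 1)

  # uncorrelated target: tiny path, full length, null fits
  y0 <- rnorm(40)
  y0 <- drop(y0 - x %*% solve(crossprod(x), crossprod(x, y0))) # orthogonal
  p0 <- lambda_path(x, y0, "gaussian", nlambda = 20)
  expect_length(p0, 20)
})

test_that("elastic net at huge penalty is the intercept-only model", {
  set.seed(12)
  g <- random_gaussian_problem(40, 6)
  fit <- enet_fit(g$x, g$y, "gaussian", lambda = 1e6, control = ctl)
  expect_equal(fit$slopes, rep(0, 6))
  expect_equal(fit$intercept, mean(g$y), tolerance = 1e-8)

  b <- random_binomial_problem(40, 6)
  fitb <- enet_fit(b$x, b$y, "binomial", lambda = 1e6, control = ctl)
  expect_equal(fitb$slopes, rep(0, 6))
  expect_equal(fitb$intercept, qlogis(mean(b$y)), tolerance = 1e-6)
})

test_that("lasso on an orthonormal standardised design soft-thresholds the covariances", {
  set.seed(13)
  n <- 32; p <- 5
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n))))[, 2:(p + 1)]
  xs <- q * sqrt(n) # centred, population sd 1, crossprod/n = I
  y <- rnorm(n, sd = 2)
  lam <- 0.15
  fit <- enet_fit(xs, y, "gaussian", alpha = 1, lambda = lam, control = ctl)
  cov_j <- drop(crossprod(xs, y - mean(y))) / n
  expected <- sign(cov_j) * pmax(abs(cov_j) - lam, 0)
  expect_equal(fit$slopes, expected, tolerance = 1e-7)
})

test_that("elastic net matches a brute-force convex solve", {
  set.seed(14)
  for (family in c("gaussian", "binomial")) {
    prob <- if (family == "gaussian") {
      random_gaussian_problem(30, 8)
    } else {
      random_binomial_problem(30, 8)
    }
    lam <- 0.07
    fit <- enet_fit(prob$x, prob$y, family, alpha = 0.95, lambda = lam,
                    control = ctl)
    oracle <- oracle_enet(prob$x, prob$y, family, alpha = 0.95, lambda = lam)
    expect_lt(max(abs(fit$slopes - oracle$slopes)), 1e-4)
    expect_lt(abs(fit$intercept - oracle$intercept), 1e-4)
  }
})

test_that("cross-validated stage-one tuning reacts to signal and noise", {
  set.seed(15)
  n <- 60; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  foldid <- rep_len(1:5, n)

  # pure noise: selection lands in the sparse upper half of the path
  y_noise <- rnorm(n)
  cvn <- cv_enet_lambda(x, y_noise, "gaussian", foldid = foldid,
                        nlambda = 50)
  expect_lte(which(cvn$path == cvn$lambda), 25)
  fitn <- enet_fit(x, y_noise, "gaussian", lambda = cvn$lambda)
  expect_lte(sum(fitn$slopes != 0), 3)

  # one strong feature: it is retained
  y_sig <- 3 * x[, 4] + rnorm(n)
  cvs <- cv_enet_lambda(x, y_sig, "gaussian", foldid = foldid, nlambda = 50)
  fits <- enet_fit(x, y_sig, "gaussian", lambda = cvs$lambda)
  expect_true(fits$slopes[4] != 0)

  # determinism under identical folds
  cv2 <- cv_enet_lambda(x, y_sig, "gaussian", foldid = foldid, nlambda = 50)
  expect_identical(cvs$lambda, cv2$lambda)
})

test_that("sign-split fit with uniform factors equals the plain lasso", {
  set.seed(16)
  for (family in c("gaussian", "binomial")) {
    prob <- if (family == "gaussian") {
      random_gaussian_problem(40, 7)
    } else {
      random_binomial_problem(40, 7)
    }
    lam <- 0.05
    ss <- signsplit_fit(prob$x, prob$y, family, lambda = lam,
                        z = rep(1, 14), control = ctl)
    en <- enet_fit(prob$x, prob$y, family, alpha = 1, lambda = lam,
                   control = ctl)
    expect_lt(max(abs(ss$slopes - en$slopes)), 1e-6)
    expect_lt(abs(ss$intercept - en$intercept), 1e-6)
  }
})

test_that("sign-split fit shrinks to zero, honours exclusions, and satisfies the KKT conditions", {
  set.seed(17)
  g <- random_gaussian_problem(35, 6)
  # very large penalty: everything zero
  big <- signsplit_fit(g$x, g$y, "gaussian", lambda = 100, z = rep(1, 12),
                       control = ctl)
  expect_equal(big$gamma, rep(0, 12))

  z <- c(1, Inf, 1, 1, Inf, 1, rep(1, 6))
  fit <- signsplit_fit(g$x, g$y, "gaussian", lambda = 0.02, z = z,
                       control = ctl)
  expect_equal(fit$gamma[c(2, 5)], c(0, 0))
  expect_lt(kkt_violation(g$x, g$y, "gaussian", 0.02, fit), 1e-7)

  b <- random_binomial_problem(35, 6)
  fitb <- signsplit_fit(b$x, b$y, "binomial", lambda = 0.03,
                        z = rep(1, 12), control = ctl)
  expect_lt(kkt_violation(b$x, b$y, "binomial", 0.03, fitb), 1e-6)
})

test_that("active sets shrink (on average) as the sign-split penalty grows", {
  set.seed(18)
  g <- random_gaussian_problem(50, 10, signal = 1.5)
  z <- rep(1, 20)
  lams <- c(0.5, 0.2, 0.05, 0.01)
  nz <- vapply(lams, function(l) {
    sum(signsplit_fit(g$x, g$y, "gaussian", lambda = l, z = z,
                      control = ctl)$slopes != 0)
  }, numeric(1))
  expect_true(all(diff(nz) >= 0))
})

test_that("deviance has its closed forms and is permutation invariant", {
  y <- c(1, 0, 1, 1)
  expect_equal(family_deviance(y, y, "gaussian"), 0)
  expect_equal(family_deviance(c(1), c(0.5), "binomial"), -2 * log(0.5))
  set.seed(19)
  yh <- runif(4)
  perm <- c(3, 1, 4, 2)
  expect_equal(family_deviance(y, yh, "binomial"),
               family_deviance(y[perm], yh[perm], "binomial"))
  # clamping keeps the value finite at predicted probabilities of 0/1
  expect_true(is.finite(family_deviance(c(1, 0), c(0, 1), "binomial")))
})

test_that("predictions apply the inverse link", {
  x <- matrix(0, 4, 3)
  expect_equal(predict_response(0, rep(0, 3), x, "binomial", "response"),
               rep(0.5, 4))
  set.seed(20)
  x <- matrix(rnorm(12), 4, 3)
  b <- rnorm(3)
  expect_equal(predict_response(1, b, x, "gaussian", "link"),
               predict_response(1, b, x, "gaussian", "response"))
  eta <- predict_response(1, b, x, "binomial", "link")
  prob <- predict_response(1, b, x, "binomial", "response")
  expect_true(all(prob > 0 & prob < 1))
  expect_identical(order(eta), order(prob))
  expect_error(predict_response(0, rep(0, 4), x, "gaussian"),
               class = "adalink_error_dim")
})
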