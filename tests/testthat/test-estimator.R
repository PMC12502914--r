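test_that("hyperparameter selection minimises and breaks ties toward less transfer", {
  tab1 <- data.frame(lambda2 = 0.3, delta_int = 0.4, delta_ext = 0.2,
                     metric = 1.5)
  expect_equal(select_hyperparameters(tab1)$lambda2, 0.3)

  tab2 <- data.frame(lambda2 = c(0.3, 0.3), delta_int = c(0, 0.2),
                     delta_ext = c(0, 0.2), metric = c(1, 1))
  sel <- select_hyperparameters(tab2)
  expect_equal(c(sel$delta_int, sel$delta_ext), c(0, 0))

  tab3 <- data.frame(lambda2 = c(0.5, 0.1), delta_int = 0, delta_ext = 0,
                     metric = c(2, 2))
  expect_equal(select_hyperparameters(tab3)$lambda2, 0.5)

  # delta_ext outranks delta_int in the tie order
  tab4 <- data.frame(lambda2 = 0.2, delta_int = c(0, 1),
                     delta_ext = c(1, 0), metric = c(3, 3))
  expect_equal(select_hyperparameters(tab4)$delta_ext, 0)
})

test_that("identically zero gaussian targets give a null model", {
  set.seed(40)
  x <- matrix(rnorm(30 * 8), 30, 8)
  y <- cbind(rep(0, 30), rep(0, 30))
  fit <- suppressWarnings(
    adalink(x, y, family = "gaussian", mode = "multi_task",
            delta_int = c(0, 1), delta_ext = c(0, 1), nlambda = 20,
            n_folds = 5, seed = 1)
  )
  expect_equal(unname(fit$slopes), matrix(0, 8, 2))
  expect_equal(fit$intercepts, c(0, 0))
})

test_that("the fit is deterministic given data and seed", {
  sim <- small_multitask(seed = 41)
  f1 <- adalink(sim$train, delta_int = c(0, 1), delta_ext = c(0, 1),
                nlambda = 20, n_folds = 5, seed = 9)
  f2 <- adalink(sim$train, delta_int = c(0, 1), delta_ext = c(0, 1),
                nlambda = 20, n_folds = 5, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$lambda2, f2$lambda2)
  expect_identical(f1$folds, f2$folds)
})

test_that("a wider exponent grid never worsens the selected CV metric", {
  sim <- small_multitask(seed = 42)
  full <- adalink(sim$train, delta_int = c(0, 0.5, 1),
                  delta_ext = c(0, 0.5, 1), nlambda = 25, n_folds = 5,
                  seed = 3)
  restricted <- adalink(sim$train, delta_int = 0, delta_ext = 0,
                        nlambda = 25, n_folds = 5, seed = 3)
  for (k in 1:2) {
    expect_lte(full$cv[[k]]$cv_min, restricted$cv[[k]]$cv_min + 1e-12)
  }
})

test_that("stage-two sparsity is bounded by the unexcluded coordinates", {
  sim <- small_multitask(seed = 43)
  fit <- adalink(sim$train, delta_int = c(0, 1), delta_ext = c(0, 1),
                 nlambda = 20, n_folds = 5, seed = 4)
  for (k in 1:2) {
    z <- fit$penalty_factors[, k]
    p <- fit$p
    usable <- is.finite(z[1:p]) | is.finite(z[(p + 1):(2 * p)])
    expect_lte(sum(fit$slopes[, k] != 0), sum(usable))
  }
})

test_that("coefficients, prediction, and serialisation are consistent", {
  sim <- small_multitask(seed = 44)
  fit <- adalink(sim$train, delta_int = c(0, 1), delta_ext = c(0, 1),
                 nlambda = 20, n_folds = 5, seed = 5)
  cm <- coef(fit)
  expect_equal(dim(cm), c(fit$p + 1, fit$q))
  expect_equal(unname(cm[1, ]), fit$intercepts)
  expect_equal(unname(cm[-1, 2]), unname(fit$slopes[, 2]))

  # training predictions equal the fitted values logged at fit time
  expect_equal(predict(fit, sim$train$x[[1]], problem = 1),
               fitted(fit, 1), tolerance = 1e-12)
  # link equals response for gaussian; zero matrix predicts the intercept
  x0 <- matrix(0, 3, fit$p)
  expect_equal(predict(fit, x0, 1, type = "link"),
               predict(fit, x0, 1, type = "response"))
  expect_equal(predict(fit, x0, 1), rep(fit$intercepts[1], 3))
  expect_error(predict(fit, matrix(0, 2, fit$p + 1), 1),
               class = "adalink_error_dim")

  # JSON round trip preserves predictions and the coefficient table
  path <- withr::local_tempfile(fileext = ".json")
  write_adalink(fit, path)
  back <- read_adalink(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(predict(back, sim$test$x[[1]], 1),
               predict(fit, sim$test$x[[1]], 1), tolerance = 1e-12)

  # coefficient table round-trips through the delimited writer
  csv <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(cm, csv)
  expect_equal(read_coefficients(csv), cm, tolerance = 1e-12)
})

test_that("prediction aligns new data by feature name", {
  sim <- small_multitask(seed = 45)
  fit <- adalink(sim$train, delta_int = c(0, 1), delta_ext = 0,
                 nlambda = 15, n_folds = 5, seed = 6)
  xte <- sim$test$x[[1]]
  shuffled <- xte[, rev(seq_len(ncol(xte)))]
  expect_equal(predict(fit, shuffled, 1), predict(fit, xte, 1))
  bad <- xte
  colnames(bad)[1] <- "not_a_feature"
  expect_error(predict(fit, bad, 1), class = "adalink_error_features")
})

test_that("an empty exponent grid is rejected", {
  sim <- small_multitask(seed = 46)
  expect_error(adalink(sim$train, delta_int = numeric(0)),
               class = "adalink_error_grid")
  expect_error(adalink(sim$train, delta_int = -0.2),
               class = "adalink_error_grid")
})

test_that("every fitted model keeps the gamma decomposition sign-exclusive", {
  fits <- list(
    adalink(small_multitask(seed = 47)$train, delta_int = c(0, 1),
            delta_ext = c(0, 1), nlambda = 20, n_folds = 5, seed = 1),
    adalink(simulate_replicate(sim_config(
      mode = "transfer", q = 2, p = 10, n_train = c(30, 40), n_test = 20,
      pi_theta = 0.3, pi_delta = 0.1, seed = 48
    ))$train, delta_int = c(0, 1), delta_ext = c(0, 1), nlambda = 20,
    n_folds = 5, seed = 2)
  )
  for (fit in fits) {
    p <- fit$p
    pair_min <- pmin(fit$gamma[1:p, , drop = FALSE],
                     fit$gamma[(p + 1):(2 * p), , drop = FALSE])
    expect_lte(max(pair_min), 1e-8)
  }
})
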