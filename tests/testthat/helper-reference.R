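# Reference pipeline: a plain position-indexed cross-validated gaussian
# lasso built directly on glmnet (two-sided penalty on X, no sign split,
# no weights), sharing only the fold assignment and the path-construction
# convention with the estimator under test.

reference_lasso_path_fit <- function(x, y, lambda_seq, thresh = 1e-15) {
  st <- oracle_standardise(x)
  f <- glmnet::glmnet(st$xs, y, family = "gaussian", alpha = 1,
                      lambda = lambda_seq, standardize = FALSE,
                      thresh = thresh, maxit = 1e6)
  beta <- as.matrix(f$beta) / st$scale
  a0 <- as.numeric(f$a0) - drop(crossprod(beta, st$centre))
  list(a0 = a0, beta = beta)
}

reference_cv_lasso <- function(x, y, foldid, nlambda, thresh = 1e-15) {
  n <- length(y)
  pred <- matrix(NA_real_, n, nlambda)
  for (f in sort(unique(foldid))) {
    tr <- foldid != f
    path_f <- lambda_path(x[tr, , drop = FALSE], y[tr], "gaussian",
                          alpha = 1, nlambda = nlambda)
    fit <- reference_lasso_path_fit(x[tr, , drop = FALSE], y[tr], path_f,
                                    thresh)
    pred[!tr, ] <- sweep(x[!tr, , drop = FALSE] %*% fit$beta, 2,
                         fit$a0, "+")
  }
  cvm <- colMeans((pred - y)^2)
  s <- which.min(cvm) # first minimum = largest penalty
  path_full <- lambda_path(x, y, "gaussian", alpha = 1, nlambda = nlambda)
  final <- reference_lasso_path_fit(x, y, path_full[seq_len(s)], thresh)
  list(intercept = final$a0[s], slopes = final$beta[, s],
       lambda = path_full[s], position = s, oof = pred[, s], cvm = cvm)
}
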