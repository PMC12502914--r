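#' @noRd
check_family <- function(family) {
  family <- match.arg(family, c("gaussian", "binomial"))
  family
}

# Inverse link: identity (gaussian) or logistic (binomial).
linkinv <- function(eta, family) {
  switch(family,
    gaussian = eta,
    binomial = plogis(eta)
  )
}

# Intercept of the null (covariate-free) model on the link scale.
null_intercept <- function(y, family) {
  mu <- mean(y)
  switch(family,
    gaussian = mu,
    binomial = qlogis(clamp_prob(mu))
  )
}

clamp_prob <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

#' Family deviance between observations and predictions
#'
#' Gaussian: mean squared error. Binomial: mean of the per-sample deviance
#' `-2 * (y * log(p) + (1 - y) * log(1 - p))`, with predicted probabilities
#' clamped away from 0 and 1 so the value is always finite. This is the
#' loss minimised during cross-validation.
#'
#' @param y Observed targets (numeric; 0/1 for binomial).
#' @param yhat Predictions on the response scale (probabilities for
#'   binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @return A single non-negative number.
#' @examples
#' family_deviance(c(1, 0), c(0.5, 0.5), "binomial") # -2 * log(0.5)
#' @export
family_deviance <- function(y, yhat, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  stopifnot(length(y) == length(yhat))
  if (family == "gaussian") {
    mean((y - yhat)^2)
  } else {
    p <- clamp_prob(yhat)
    mean(-2 * (y * log(p) + (1 - y) * log(1 - p)))
  }
}

#' Predictions from an intercept and slope vector
#'
#' @param intercept Scalar intercept.
#' @param slopes Length-p slope vector.
#' @param x Matrix with p columns.
#' @param family `"gaussian"` or `"binomial"`.
#' @param type `"link"` for the linear predictor, `"response"` for its
#'   inverse-link transform.
#' @return Numeric vector with one entry per row of `x`.
#' @export
predict_response <- function(intercept, slopes, x,
                             family = c("gaussian", "binomial"),
                             type = c("response", "link")) {
  family <- match.arg(family)
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != length(slopes)) {
    adalink_stop(sprintf(
      "feature matrix has %d columns but %d slopes were supplied",
      ncol(x), length(slopes)
    ), "adalink_error_dim")
  }
  eta <- drop(intercept + x %*% slopes)
  if (type == "link") eta else linkinv(eta, family)
}
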