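# Small random problem generators used across the unit tests. Everything
# is seeded by the caller.

random_gaussian_problem <- function(n = 30, p = 5, signal = 1) {
  x <- matrix(rnorm(n * p), n, p)
  beta <- signal * rnorm(p) * rbinom(p, 1, 0.5)
  y <- drop(x %*% beta) + rnorm(n)
  list(x = x, y = y, beta = beta)
}

random_binomial_problem <- function(n = 30, p = 5, signal = 1) {
  repeat {
    x <- matrix(rnorm(n * p), n, p)
    beta <- signal * rnorm(p) * rbinom(p, 1, 0.5)
    y <- rbinom(n, 1, plogis(drop(x %*% beta)))
    if (sum(y) >= 3 && sum(1 - y) >= 3) break
  }
  list(x = x, y = y, beta = beta)
}

# Random penalty-factor vector of length 2p mixing finite values and hard
# exclusions, never excluding everything.
random_penalty_factors <- function(p, prob_inf = 0.25) {
  repeat {
    z <- exp(rnorm(2 * p, sd = 0.7))
    z[runif(2 * p) < prob_inf] <- Inf
    if (any(is.finite(z))) return(z)
  }
}

# A small multi-task gaussian problem set with a shared signal.
small_multitask <- function(n = 40, p = 12, q = 2, seed = 1) {
  simulate_replicate(sim_config(
    mode = "multi_task", q = q, p = p, n_train = n, n_test = 50,
    pi_theta = 0.25, pi_delta = 0.1, seed = seed
  ))
}
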