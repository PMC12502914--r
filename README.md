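# adalink

Sparse multi-task and transfer learning for high-dimensional regression
via sign-specific adaptive penalisation.

## The problem

In omics-scale prediction problems (p features ≫ n samples) a single
dataset often carries too little information to estimate an accurate
sparse model. When several *related* problems are available — either
several targets measured on the **same** samples (multi-task learning)
or the same kind of target measured on **disjoint** sample sets
(transfer learning) — their effect vectors are expected to be positively
correlated, and sharing information between them can improve both
prediction and feature selection. `adalink` is aimed at statisticians
and computational biologists who want sparse, interpretable per-problem
models (a handful of selected features with signed effects) rather than
a single pooled fit.

## The method

Each problem k is a generalised linear model

    h(E[y | x]) = β₀ₖ + Σⱼ βⱼₖ xⱼ ,   h = identity (gaussian) or logit (binomial).

**Stage 1.** Every problem is fit separately with a lasso-like elastic
net (mixing α = 0.95), the penalty λ₁ₖ tuned by 10-fold
cross-validation. This yields initial coefficients β̂ⱼₖ.

**Stage 2.** Each slope is decomposed into a positive and a negative
part, βⱼₖ = γⱼₖ − γ_{p+j,k} with γ ≥ 0, and the problem is refit as a
weighted *non-negative* lasso on the column-augmented design [X | −X]
with penalty

    λ₂ₖ Σⱼ γⱼₖ / [ (wⱼₖ^int)^δint + (wⱼₖ^ext)^δext ] ,

where the **internal weights** carry sign-specific evidence from the
problem's own stage-1 fit (wⱼₖ^int = max(0, β̂ⱼₖ) for a positive final
effect, |min(0, β̂ⱼₖ)| for a negative one) and the **external weights**
pool the same quantities over the *other* problems. The scaling
exponents δint, δext ∈ {0, 0.2, …, 1} and λ₂ₖ are tuned per problem by a
cross-validated grid search (with the convention 0⁰ = 1, a zero exponent
switches that information source off). A zero prior weight means the
coordinate direction is excluded outright. The estimator therefore
contains the standard lasso (δint = δext = 0) and the internal-only
adaptive lasso (δext = 0) as exact special cases, and the grid search
can always fall back to them.

## Worked example

Simulate three related gaussian problems on shared samples (p = 100
features with AR(1) correlation 0.5, 9–10 weak effects per problem of
which ~5 are shared, unit noise), fit the model, and compare it with its
own lasso reduction on 2000 hold-out samples:

```r
library(adalink)

sim <- simulate_replicate(sim_config(
  mode = "multi_task", q = 3, p = 100, n_train = 100, n_test = 2000,
  pi_theta = 0.05, pi_delta = 0.025, seed = 42))

fit <- adalink(sim$train, seed = 42)
fit
#> adalink fit: multi-task, gaussian family, 3 problem(s), p = 100
#>   problem   n lambda1 lambda2 delta_int delta_ext nonzero
#>  problem1 100 0.07068 0.01758       1.0       1.0      40
#>  problem2 100 0.10820 0.03318       0.6       1.0      28
#>  problem3 100 0.11450 0.02710       1.0       0.8      33

red <- adalink(sim$train, delta_int = 0, delta_ext = 0, seed = 42)  # plain CV lasso
sapply(1:3, function(k)
  test_mse(sim$test$y[[k]], predict(fit, sim$test$x[[k]], k)) /
  test_mse(sim$test$y[[k]], predict(red, sim$test$x[[k]], k)))
#> [1] 0.470 0.525 0.557
```

Every problem selected nonzero exponents, i.e. the grid search chose to
use both the problem's own stage-1 fit and the other problems' fits as
prior information; the hold-out mean squared error drops to roughly half
of the lasso's, with far fewer nonzero coefficients than the lasso
selects on the same data. `coef(fit)` returns the (p+1) × q coefficient
table, `summary(fit)` the per-problem tuning report, and
`write_adalink()` / `read_adalink()` serialise a fit to JSON.

A file-based workflow (`cmd_fit`, `cmd_predict`, `cmd_simulate`,
`cmd_evaluate`, and the `inst/cli/adalink.R` dispatcher) covers the same
steps for delimited text inputs; `run_study()` runs seeded
simulation-study replicates comparing the method against its lasso
reduction.

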