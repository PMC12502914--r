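---
title: "Sparse multi-task and transfer learning by sign-specific adaptive penalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multi-task and transfer learning by sign-specific adaptive penalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`adalink` estimates q related generalised linear models that share the
same p features. In *multi-task* mode the problems also share their n
samples (one feature matrix, q targets); in *transfer* mode each problem
has its own disjoint sample set of size n_k. Supported families are
gaussian (identity link, squared-error loss) and binomial (logit link,
deviance loss). The method's premise is that the problems' effect
vectors are positively correlated: a feature with, say, a positive
effect in one problem is more likely to have a positive (or zero) than a
negative effect in the others. The procedure shares exactly that kind of
information — feature selection, effect direction, and effect size —
while still fitting every problem separately, so an unrelated problem
can at worst be ignored (see the reduction properties below), not
actively harm the others beyond what its noise contributes through the
tuning step.

### Stage 1: separate elastic net fits

Each problem is first fit alone with an elastic net penalty
`lambda1 * sum(alpha*|b| + (1-alpha)/2 * b^2)` at mixing
`alpha_init = 0.95`. The near-lasso mixing keeps the initial fits sparse
while allowing more than n_k selected features and stabilising groups of
strongly correlated features, which matters for the AR(1)-type
correlation structure typical of omics predictors. `lambda1` is tuned
once per problem by F-fold cross-validation (pooled out-of-fold
deviance, minimum rule) on the full data and then held fixed throughout
stage 2, exactly as the two-stage procedure prescribes; the mild
information reuse this implies is part of the method's design. A
documented alternative for degenerate stage-1 fits (all slopes zero, as
can happen with many weak effects) would be a ridge refit; `adalink`
does not do this automatically — a null stage-1 fit simply produces
uniform prior weights in that problem, which is a well-defined fallback.

### Stage 2: sign-split weighted non-negative lasso

Every slope is decomposed as `b_j = g_j - g_{p+j}` with both parts
non-negative, and the problem is refit on the column-augmented design
`[X | -X]` under the linear penalty `lambda2 * sum_j z_j * g_j`. The
penalty factors are the reciprocal prior weights

    z_j = 1 / ( (w_int_j)^delta_int + (w_ext_j)^delta_ext ),

where the internal weights are the positive/negative parts of the
problem's own stage-1 coefficients and the external weights are the
per-direction sums of the other problems' stage-1 coefficients. Because
the two directions of a feature are perfectly collinear, at most one of
`g_j`, `g_{p+j}` is nonzero at the optimum — the fit never pays for both
directions, and the collapsed slope is unambiguous. Two conventions
matter here:

* `0^0 = 1`, applied per term: a zero exponent makes that information
  source contribute a constant 1 for every coordinate, i.e. switches it
  off entirely rather than excluding anything.
* A prior weight of exactly zero (feature unsupported in that direction
  by either source at positive exponents) maps to an infinite penalty
  factor, implemented as a *hard exclusion*: the coordinate is dropped
  before fitting rather than given a huge finite penalty, which avoids
  ill-conditioning and makes "excluded" exact.

Finite penalty factors are rescaled to average exactly one. This keeps
the scale of `lambda2` comparable across all 36 exponent pairs of the
grid, so one common path-position axis can be cross-validated; it also
makes the factors invariant to rescaling all weights, which is what
makes the delta = 0 reduction *exactly* a uniform-penalty lasso.

## Hyperparameter tuning

`delta_int` and `delta_ext` take values in `{0, 0.2, 0.4, 0.6, 0.8, 1}`
by default; exponents below one dampen large weights relative to small
ones. `lambda2` runs along a log-spaced path of `nlambda = 100` values
(at most 100 by convention) from the analytic null-model bound, with
`lambda_min/lambda_max = 0.01` when p > n and `1e-4` otherwise. For the
sign-split path the p-versus-n comparison deliberately uses the number
of *original* features, not the 2p augmented columns, so the reduction
and a plain lasso on X share an identical path.

The grid is scored by F-fold cross-validation (default F = 10) on one
shared fold assignment per problem set:

* **multi-task**: for each fold, stage 1 is refit for *every* problem on
  the retained rows (the samples are shared, so excluding a fold
  excludes it everywhere), and the weights feeding the held-out
  predictions are computed from those fold-excluded coefficients;
* **transfer**: stage-1 coefficients are computed once per full dataset,
  and within a fold of problem k only problem k's own column is refit on
  its reduced dataset — the other problems' coefficients legitimately
  use their full data, because those samples are never held out.

Because the penalty factors change with the exponent pair (and, through
the fold refits, with the fold), the `lambda2` path is rebuilt from the
fold-training data for every (fold, pair) combination. Cross-validation
curves are therefore indexed by *path position*; out-of-fold predictions
are pooled over folds into one deviance per (pair, position) candidate,
and the winning position is re-solved on the full-data path of the
winning pair. The minimum-CV rule is used throughout (no
one-standard-error rule), with exact ties broken toward `delta_ext = 0`
first (prefer no transfer), then `delta_int = 0` (prefer no adaptation),
then the larger, sparser `lambda2`.

Two reduction properties pin the scheme down and are enforced by tests:
with both exponent grids restricted to `{0}` the whole pipeline
reproduces a plain cross-validated lasso on the same folds and path to
numerical accuracy; and with `delta_ext` restricted to `{0}` the fit of
each problem is bit-identical under replacement of the other problems'
targets, i.e. depends on its own data only.

## Randomness, folds, and determinism

All randomness flows from one integer seed. The only stochastic step in
fitting is the fold assignment: balanced partitions (fold sizes differ
by at most one), one shared partition in multi-task mode, and
per-problem partitions in transfer mode whose sub-seeds depend only on
the seed and the problem index — this is what makes the transfer-mode
locality property exact. For the binomial family folds are stratified by
default, balancing class counts across folds up to rounding; rare
minority classes (fewer members than folds) legally leave some folds
without minority samples, and the pooled deviance metric remains
defined. In multi-task mode one shared partition cannot stratify all q
targets simultaneously, so stratification uses the first problem's
target; pass `stratify = FALSE` to disable. Refitting with the same
data, grids, and seed is bit-reproducible.

## Numerical choices

* The convex subproblems (elastic net paths, and the sign-split fit as a
  non-negative weighted lasso on `[X | -X]` with zero lower limits) are
  solved by coordinate descent via glmnet, with features standardised
  *outside* the solver to unit population variance (both directions of a
  feature share one scale) and coefficients returned in original units.
  Correctness of the sign-split stage is audited in the test suite
  against an independent generic convex solve (projected L-BFGS-B on the
  identical objective) plus explicit KKT checks.
* Convergence threshold `1e-9` (relative to the null deviance on the
  standardised scale), `1e5` coordinate passes. The reduction-identity
  tests tighten this to `1e-15`; the defaults favour speed at accuracy
  far below any reported quantity. If the deepest path values fail to
  converge within the pass budget (binomial fits near separation), the
  converged prefix is kept and extended by its last fit, so path
  positions stay aligned; a genuinely failed solve raises an error with
  diagnostics.
* For the gaussian family the coordinate-descent engine works on a
  unit-variance target, so at mixing below one the ridge component of
  the stage-1 penalty is effectively scaled by the target's inverse
  standard deviation. The package adopts this convention (stage 1 is
  internally consistent because `lambda1` is selected under it); the L1
  component, and hence the entire stage-2 objective, is exact in the
  given units.
* Degenerate inputs: a constant gaussian target yields a single-value
  degenerate path with a warning and a null fit; a target merely
  uncorrelated with every feature yields a full-length path of tiny
  values whose fits are all null; constant feature columns are excluded
  from penalised fitting and absorbed into the intercept.
* The pair `z_j = z_{p+j} = 0` cannot arise (prior weights are finite,
  so factors are positive or infinite); this is asserted, not handled.

## What the simulation emulates — and what it does not

`simulate_replicate()` draws the reference generating process: rows of X
are mean-zero Gaussian with correlation `rho^|j-l|` (`rho = 0.5`),
generated by the exact O(np) AR(1) recursion rather than a p×p Cholesky
factor (the equivalence is a tested property); effects are
`B[,k] = theta + Delta[,k]` with spike-and-slab entries
(Bernoulli indicator times standard normal, inclusion probabilities
`pi_theta` shared, `pi_delta` specific); targets add unit Gaussian
noise. Defaults mirror the reference study design (q = 3, p = 200,
n = 100 multi-task, n = 50/100/200 transfer); the packaged default
hold-out is 2000 samples per problem rather than 10000 to keep
desk-scale runs light (`n_test = 10000` restores the full size — the
hold-out size only affects the Monte-Carlo error of the test MSE). A
binomial variant (targets Bernoulli(logistic(XB))) is provided as a
labelled extension beyond the reference design.

Passing tests on this generator demonstrates the method's behaviour
under Gaussian, homoscedastic, moderately autocorrelated designs with
exactly sparse effects. Real omics data differ in ways the generator
does not emulate — heavy-tailed and heteroscedastic expression values,
block rather than banded correlation, batch structure, and effects that
are small-but-dense rather than sparse — so simulation results bound
expectations rather than guarantee them.

## The study harness

`run_study()` compares the full-grid estimator against its own
`delta = {0} x {0}` reduction on identical data and folds. Using the
built-in reduction rather than an external lasso implementation
guarantees that paths, folds, standardisation, and selection rules are
identical, so the reported hold-out MSE ratio isolates the effect of
adaptive information sharing; note the reduction's stage 2 is a pure L1
fit (the stage-1 mixing 0.95 only influences the, then unused, weights).
Metrics follow the evaluation design: hold-out MSE (and its ratio to the
reduction), number of nonzero coefficients, sign precision (correct
signs among selected features, reported as missing for empty models so
means are not biased either way), and rank-based ROC-AUC for binomial
problems. Problems are averaged first within a replicate, then across
replicates. The packaged study sizes (p = 100, n = 100, 2000 hold-out
samples, 10 replicates multi-task / 5 transfer, seeded) were chosen as
the smallest configuration in which the shared-effects benefit is
clearly resolved against Monte-Carlo noise; the full-size design is a
`sim_config()` call away.

## Known limitations

* Families are gaussian and binomial only (no Cox, Poisson,
  multinomial); designs are dense matrices.
* All q problems receive equal weight in the external sums; per-source
  weighting of more or less informative problems is out of scope.
* The grid search refits the stage-2 path for every (fold, pair)
  combination — roughly `q * F * 36` path fits per model — which is
  exact but makes fitting an order of magnitude slower than a single
  cross-validated lasso.
* `lambda1` is tuned on the full data before the stage-2
  cross-validation (the procedure's own design), so the stage-2 CV
  metric is not a fully honest generalisation estimate; hold-out
  evaluation in the study harness is unaffected.
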