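---
title: "Methods: joint Cox models with shared row sparsity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint Cox models with shared row sparsity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how `mtlcox` defines, fits and validates its model:
the assumptions behind each component, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic
validation can show about real cohort data.

## Model and assumptions

Each disease `k` is a proportional-hazards model
`h_k(t | x) = h_0k(t) exp(x β_k)` on right-censored follow-up measured in
years from enrollment.  The assumptions inherited from the Cox framework
apply per disease: proportional hazards (covariate effects constant in
time), independent censoring, and covariates fixed at baseline.  Diseases
are modeled marginally — a subject can appear in several cohorts, and no
competing-risk adjustment is made between diseases.

The tasks are coupled only through the penalty.  With `B` the `P x K`
coefficient matrix (features in rows), the estimate minimizes

```
f(B) = sum_k NLL_k(beta_k) / N_k + lambda * sum_p ||B[p, ]||_2
```

The L2,1 penalty encodes the substantive assumption that the diseases
share risk factors: a feature row is either active for all tasks or
zeroed for all tasks.  When the diseases are in fact unrelated this
assumption hurts rather than helps; the simulator's `jitter_sd` knob
exists precisely to probe that regime.

Each task's likelihood is normalized by its subject count `N_k`, so
cohorts of different sizes contribute comparably to the joint objective;
normalization by event count is available (`normalization = "events"`)
for settings with very unequal censoring, since with heavy censoring the
effective information per subject is driven by events rather than
enrollment.

## Partial likelihood and ties

The negative log partial likelihood, its gradient and its Hessian are the
classical sums over events of (event covariate minus exp-weighted
risk-set mean) and the matching weighted risk-set covariance.  Tied event
times are handled by the Breslow approximation throughout — every event
in a tie block reuses the full risk-set denominator — because it is the
convention under which the analytic gradient and Hessian stay exact as
written.  Efron's correction is more accurate with many ties but is
deliberately out of scope; inputs with heavy tying (e.g. times rounded to
whole years) should be jittered or treated with care.

All likelihood code sorts each task once by decreasing time and
accumulates risk-set sums as reverse cumulative sums (`O(N·P)` per
gradient evaluation), with log-sum-exp stabilization so large linear
predictors cannot overflow.

## Solver

The objective is convex (each per-task NLL has a positive semidefinite
Hessian; the penalty is a norm) but non-smooth, so it is minimized by
proximal gradient with momentum:

* **Proximal operator.**  The L2,1 prox separates over rows and has the
  closed form `B[p,] = G[p,] * max(0, 1 - tau / ||G[p,]||_2)`; rows at or
  below the threshold become exactly zero.  The implementation is checked
  against a numerical 1-D minimization oracle in the test suite.
* **Line search.**  The inverse step `gamma` starts at 1 and doubles
  until the quadratic majorization
  `L(B_new) <= L(S) + <grad, B_new - S> + gamma/2 ||B_new - S||_F^2`
  holds at the search point `S`.  `gamma` is carried between iterations.
* **Momentum.**  The standard accelerated recursion
  `q_j = (1 + sqrt(1 + 4 q_{j-1}^2)) / 2` with extrapolation weight
  `(q_{j-1} - 1) / q_j`, starting from `q_0 = 1` (first step is plain
  proximal gradient).  Plain accelerated steps are not monotone, so if an
  extrapolated step would increase the objective the momentum is
  restarted and the step retaken from the current iterate; the recorded
  objective history is therefore nonincreasing by construction.
* **Stopping.**  Relative objective change below `1e-6` or relative
  coefficient change (Frobenius) below `1e-5`, capped at 5000 iterations
  (a looser `1e-5`/`1e-4` is used inside cross-validation path fits,
  where warm starts across the penalty grid make high accuracy per point
  unnecessary).  Non-convergence returns the best iterate with a flag.
* **Initialization.**  `B = 0` for a cold start — deterministic and
  consistent with the `lambda_max` stationarity property; path fits warm
  start from the previous penalty.

A fixed-step, non-accelerated mode (`accelerate = FALSE`,
`line_search = FALSE`) exists so the `O(1/j)` convergence guarantee of
proximal gradient descent with step `t <= 1/L` can be verified directly;
the test suite checks the envelope `f(B_j) - f* <= ||B_0 - B*||^2/(2 t j)`
against a tight-tolerance optimum on small problems.

## Penalty path and selection

The grid is geometric with 50 points from `1 * lambda_max` down to a
ratio of 0.01, where `lambda_max = max_p ||row p of grad L(0)||_2` is the
smallest penalty at which the zero matrix is stationary.  The three
settings (path length 50, ratio 0.01, first-point scale 1) are the
method's standard search-grid configuration.

Selection uses 5-fold cross-validation with event-stratified folds
(events and censored subjects spread evenly; folds are resampled if any
training split would lose all events of some task).  Each held-out fold
is scored by the concordance index of the linear predictor, averaged over
tasks and then folds.  Two properties of this criterion drove the
selection rule:

* The C-index is invariant to rescaling each task's coefficients, so
  once the correct rows are active the CV curve is essentially flat in
  `lambda`; a plain argmax is then decided by noise and can wander far
  down the path.
* On pure-noise data every penalty that zeroes `B` scores exactly 0.5,
  while occasional noise fits score slightly above or below.

The default is therefore the **one-standard-error rule**: the largest
penalty whose mean CV concordance is within one fold standard error of
the maximum.  It resolves the plateau toward parsimony, returns the empty
model on pure noise, and is the familiar convention from penalized
regression practice.  `one_se = FALSE` restores the plain argmax (ties
toward the larger penalty).

## Debiased (relaxed) coefficients

Group soft-thresholding buys row sparsity at the price of shrinking the
surviving rows toward zero, so the penalized point estimate is biased by
design.  For *prediction and ranking* this is harmless (within a task the
ranks of `x'beta` are unchanged by proportional shrinkage) and the
penalized fit is the default.  For *coefficient reporting and parameter
recovery* the package follows the relaxed-fit convention: keep the
selected rows, refit each task by unpenalized Newton Cox restricted to
those features, and leave the discarded rows at exact zero
(`relax = TRUE` in `cv_mtl_cox()`, or `relax_fit()` directly).  The
support is untouched by the refit; only the values change.  The recovery
study in the acceptance suite reports the debiased estimate for this
reason.

## Baseline hazard and absolute risk

The cumulative baseline hazard is the Breslow estimator
`H_0(t) = sum_{T_i <= t} d_i / sum_{s in R(T_i)} exp(x_s beta)`, the
canonical partner of the partial likelihood (with `beta = 0` it reduces
to Nelson–Aalen).  Absolute risk at horizon `h` uses the exact
proportional-hazards transform `AR = 1 - exp(-H_0(h) e^{x beta})` rather
than any numerical integration of the hazard.  Horizons beyond the last
observed follow-up hold the hazard at its final step and warn, since the
estimator carries no information there.

## Personalized risk layer

* **Basis risk** is the mean absolute risk within an age group (default
  bins 40–49, 50–59, 60–69, 70+), per disease and horizon.  `RAR =
  AR / basis`, `EAR = AR - basis`; by construction the within-group mean
  of RAR is 1 and of EAR is 0, which the tests assert as exact
  identities.  `RAR` is reported as undefined (`NA`) when the basis risk
  is zero rather than propagating infinities.  `EAR` is also provided in
  percentage points (`ear_pct`), the scale usually quoted in reports.
* **Strata** use the 33%, 50% and 66% quantiles of absolute risk (type-7
  linear interpolation, the default convention of `quantile()`), computed
  per disease, age group and horizon; a pooled-over-ages mode exists
  because the grouping choice is genuinely open — per-age-group is the
  default since basis risk itself is age-specific.  A risk exactly at the
  33% boundary is labeled low (inclusive downward); when all boundaries
  coincide everything is labeled average.
* **Ranking** orders diseases per subject by decreasing absolute risk at
  one horizon, ties broken by disease name so the result is independent
  of input ordering.

## Evaluation metrics

* **C-index**: comparable pairs are (event subject `i`, any subject `j`
  with strictly longer follow-up); tied scores count one half.  Scores
  are linear predictors — within a task any strictly monotone transform
  (e.g. absolute risk at a fixed horizon) gives the identical value.
* **Horizon binarization**: positives are events by the horizon,
  negatives are subjects still under observation past it; subjects
  censored before the horizon carry no label and are *excluded*, not
  treated as negatives — censoring-aware inverse-probability weighting is
  out of scope, and the exclusion is flagged in the returned mask.  The
  default evaluation horizon is 5 years.
* **AUC** via the rank (Mann–Whitney) formulation with midranks for
  ties; the reported cutoff maximizes the Youden index along the ROC,
  keeping the highest threshold on ties.  The identity `youden =
  sensitivity + specificity - 1` is exact.
* **Paired Wilcoxon** comparisons are two-sided on disease-by-fold
  pairs, zero differences dropped, exact null distribution for at most 25
  untied pairs, normal approximation with continuity (and tie) correction
  otherwise — i.e. the `stats::wilcox.test` conventions.

## Synthetic cohorts

The generator emulates the structure the estimator assumes: features
multivariate normal with exchangeable correlation (`rho = 0.2`), event
times from a Weibull proportional-hazards model
`T = (-log U / (scale * e^{x beta}))^{1/shape}` (defaults shape 1.5,
scale 0.1 — a rising hazard with a median event time of a few years on
the standardized-feature scale), and administrative censoring uniform on
a window calibrated by bisection so the realized censoring fraction lands
within 2 percentage points of the target (default 30%).  The true
coefficient matrix has alternating-sign effects of magnitude 0.8 on the
first `support` rows (default 5 of 20), exact zeros elsewhere, and an
optional per-task jitter controlling task relatedness.  An optional age
covariate (uniform 40–80, entering as `(age - 60)/10` with coefficient
0.5) gives the risk layer an age gradient to detect.  The seed fully
determines the output.

Reference problem sizes used throughout validation, chosen as realistic
desk-scale analogs of multi-disease cohort modeling: the recovery study
uses K = 3 tasks, P = 20 features, n = 1000 subjects per task over 10
seeds; the multitask-advantage study uses K = 5 related tasks of n = 150
— small enough per task that borrowing strength is expected to pay — with
held-out cohorts of n = 500 for scoring.

What the simulator does **not** emulate: real marginal feature
distributions (categorical recodings, skewness), informative or
covariate-dependent censoring, non-proportional hazards, measurement
error, and between-disease dependence at the subject level.  Passing
recovery and advantage tests therefore demonstrates correctness of the
estimator and its implementation under its own assumptions, not
performance on any particular cohort.

## Degenerate inputs and edge rules

Tasks with zero events are rejected (the partial likelihood is
undefined); cross-validation refolds until every split keeps events in
every task.  Zero-variance continuous features are centered but not
scaled, with a warning.  Missing values are rejected at load time
(complete-case analysis) with a per-row report.  Monotone likelihoods
(separation) in the Newton baseline are capped at |beta| = 20 with a
warning.  Times supplied in days are converted at 365.25 days per year.
Standardization uses the sample (n − 1) standard deviation and can be
pooled across tasks (default — the shared feature registry suggests one
population) or per task.

## Known limitations

Single penalty for all rows (no per-feature weighting); no trace-norm or
fused alternatives to the L2,1 coupling; no time-varying covariates,
stratified baselines, or Efron ties; binary conversion discards
early-censored subjects rather than reweighting; the Weibull baseline is
fit per task only.  These are boundaries of scope, not of the design —
each would slot behind the existing module surfaces.
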