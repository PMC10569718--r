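# mtlcox — multitask Cox models with shared feature selection

`mtlcox` estimates **K related Cox proportional-hazards models jointly**.
Epidemiological cohorts often follow the same subjects for several chronic
diseases that share risk factors (smoking, age, lipids, ...), yet the
standard workflow fits each disease in isolation, discarding that shared
structure.  `mtlcox` couples the per-disease models through an L2,1
penalty on the coefficient matrix so that feature selection is performed
*once, across diseases*, and each disease borrows strength from the
others — which matters most when individual cohorts are small or heavily
censored.

The package is aimed at biostatisticians working with right-censored
multi-disease cohort data (one table of subject, follow-up time, event
indicator, and shared features per disease), and at methodologists who
want a tested reference implementation of the estimator with all of its
surrounding machinery.

## The model

For disease (task) `k` with coefficients `β_k`, the Cox hazard is
`h_k(t | x) = h_0k(t) exp(x β_k)`.  Writing `B = [β_1 … β_K]` (features in
rows), the joint estimate minimizes the penalized, sample-size-normalized
negative log partial likelihood

```
min_B  Σ_k NLL_k(β_k) / N_k  +  λ ‖B‖_{2,1},      ‖B‖_{2,1} = Σ_p ‖β^p‖_2
```

where `β^p` is row `p` of `B`.  The row-wise L2 norm inside an L1 sum
zeroes *entire rows*: a feature is kept or dropped for all diseases at
once.  The objective is convex and is solved by accelerated proximal
gradient (FISTA-style momentum, backtracking line search on the inverse
step size, momentum restart on any objective increase), using the
closed-form row group soft-thresholding proximal operator.  The penalty
is chosen on a geometric path of 50 values anchored at the data-derived
`λ_max` (ratio 0.01, first point at `1·λ_max`) by 5-fold event-stratified
cross-validated concordance with a one-standard-error parsimony rule.

Around the estimator the package provides:

* Breslow baseline hazards and absolute risk `AR = 1 − exp(−H_0(h) e^{xβ})`
  at fixed horizons (1/3/5/7 years by default);
* a personalized risk layer: age-group basis risk, relative (`RAR`) and
  excess (`EAR`) absolute risk, 33/50/66% quantile risk strata, and
  per-subject disease ranking;
* censoring-aware evaluation: Harrell's C-index, fixed-horizon ROC/AUC
  with Youden-optimal cutoff, sensitivity/specificity, and paired
  Wilcoxon signed-rank comparisons;
* single-task baselines: Newton Cox, Cox-LASSO (same solver, K = 1),
  Weibull proportional hazards;
* a simulator of K related right-censored cohorts with known shared
  sparse support, so every claim is testable by parameter recovery.

## Worked example

Simulate three related cohorts (500 subjects each, 30% censoring, five
truly active features plus an age effect), fit the cross-validated
multitask model, and inspect recovery and personalized risks:

```r
library(mtlcox)

sim <- simulate_tasks(sim_config(K = 3, P = 20, support = 5, n = 500,
                                 censoring = 0.3, age = TRUE, seed = 42))
set.seed(42)
cv <- cv_mtl_cox(sim$dataset, relax = TRUE)
cv
#> <cv_mtl_cox: 50 penalties, lambda_opt=0.2655 (cv C-index 0.823)>
#> <mtl_cox_fit: lambda=0.2655, 6/21 active feature rows, 11 iterations>

rec <- recovery_report(cv$fit$B, sim$B_true)
sprintf("support F1 %.2f, RMSE on true support %.3f", rec$f1, rec$rmse_support)
#> "support F1 1.00, RMSE on true support 0.069"

round(cv$fit$B[rowSums(cv$fit$B^2) > 0, ], 3)
#>             task1  task2  task3
#> x1          0.884  0.747  0.857
#> x2         -0.711 -0.913 -0.861
#> x3          0.833  0.897  0.829
#> x4         -0.828 -0.753 -0.728
#> x5          0.915  0.881  0.721
#> age_scaled  0.519  0.523  0.464
```

The fitted model selects exactly the six truly active rows (out of 21)
and estimates their effects to within sampling error; all other rows are
exactly zero in every task.  The personalized risk layer turns the fit
into subject-level reports:

```r
X  <- sim$dataset$tasks[[1]]$X
rt <- risk_table(cv$fit, X, horizons = c(1, 3, 5, 7))
basis <- basis_risk(rt, sim$ages[[1]])                  # age-group mean AR
prof  <- relative_and_excess(rt, basis, sim$ages[[1]])
head(prof[prof$horizon == 3, ], 4)
#>      id disease horizon age_group     ar basis_ar   rar    ear ear_pct
#> 1501  1   task1       3       70+ 1.0000    0.590 1.696  0.410    41.0
#> 2001  1   task2       3       70+ 1.0000    0.647 1.546  0.353    35.3
#> 2501  1   task3       3       70+ 1.0000    0.623 1.606  0.377    37.7
#> 1662  2   task1       3     40-49 0.0722    0.304 0.237 -0.232   -23.2
```

Subject 2 carries a 3-year absolute risk of 7.2% for disease `task1` —
0.24 times the average of their age group (`rar`), i.e. 23 percentage
points below it (`ear_pct`).  `risk_strata()` + `stratify()` label each
subject low/average/high against the 33/50/66% quantiles, and
`rank_diseases(rt, horizon = 5)` orders the diseases per subject by
absolute risk.

`run_experiment()` wires everything into the full benchmark (shared
event-stratified folds, nested penalty selection, metrics and Wilcoxon
comparison tables); `inst/scripts/mtlcox-benchmark.R` exposes it on the
command line with `simulate`, `benchmark` and `risk-report` subcommands.

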