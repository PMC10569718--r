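# one small fitted model reused across the risk-layer tests
fit_demo <- local({
  sim <- simulate_tasks(sim_config(K = 3, P = 6, support = 2, n = 250,
                                   age = TRUE, seed = 71))
  list(sim = sim,
       fit = mtl_cox(sim$dataset, 0.2 * lambda_max(sim$dataset)))
})

test_that("risk tables reproduce the baseline subject and horizon monotonicity", {
  fit <- fit_demo$fit
  X <- fit_demo$sim$dataset$tasks[[1]]$X[1:40, ]
  rt <- risk_table(fit, X, horizons = c(1, 3, 5, 7))
  expect_true(all(rt$ar >= 0 & rt$ar <= 1))
  # AR nondecreasing across horizons for every subject x disease
  for (sp in split(rt, list(rt$id, rt$disease))) {
    expect_true(all(diff(sp$ar[order(sp$horizon)]) >= -1e-12))
  }
  # baseline subject (all features zero): AR = 1 - S0(h)
  rt0 <- risk_table(fit, matrix(0, 1, ncol(X),
                                dimnames = list(NULL, colnames(X))),
                    horizons = 3)
  for (k in seq_along(fit$task_names)) {
    expect_equal(rt0$ar[rt0$disease == fit$task_names[k]],
                 1 - exp(-baseline_cumhaz(fit$baselines[[k]], 3)))
  }
  # no accidental normalization across diseases
  s <- with(rt[rt$horizon == 3, ], tapply(ar, id, sum))
  expect_gt(stats::sd(s), 0)
})

test_that("basis risk averages within age groups and grows with age effect", {
  fit <- fit_demo$fit
  sim <- fit_demo$sim
  X <- sim$dataset$tasks[[1]]$X
  age <- sim$ages[[1]]
  rt <- risk_table(fit, X, horizons = c(3, 5))
  basis <- basis_risk(rt, age)
  # single-subject group equals that subject's AR
  i1 <- which.min(age)
  rt1 <- risk_table(fit, X[i1, , drop = FALSE], horizons = 3)
  b1 <- basis_risk(rt1, age[i1])
  expect_equal(b1$basis_ar, rt1$ar[match(paste(b1$disease, b1$horizon),
                                         paste(rt1$disease, rt1$horizon))])
  # age carries positive hazard: basis risk increases across age groups
  for (d in unique(basis$disease)) {
    for (h in unique(basis$horizon)) {
      b <- basis[basis$disease == d & basis$horizon == h, ]
      b <- b[order(b$age_group), ]
      if (nrow(b) >= 3) expect_gt(b$basis_ar[nrow(b)], b$basis_ar[1])
    }
  }
})

test_that("relative and excess risk identities hold within every age group", {
  fit <- fit_demo$fit
  sim <- fit_demo$sim
  X <- sim$dataset$tasks[[1]]$X
  age <- sim$ages[[1]]
  rt <- risk_table(fit, X, horizons = c(1, 3))
  basis <- basis_risk(rt, age)
  prof <- relative_and_excess(rt, basis, age)
  expect_true(all(prof$rar >= 0, na.rm = TRUE))
  expect_equal(prof$rar * prof$basis_ar, prof$ar)   # exact by construction
  # per age group x disease x horizon: mean RAR = 1 and mean EAR = 0
  agg <- aggregate(cbind(rar, ear) ~ disease + age_group + horizon,
                   data = prof, FUN = mean)
  expect_equal(agg$rar, rep(1, nrow(agg)), tolerance = 1e-12)
  expect_equal(agg$ear, rep(0, nrow(agg)), tolerance = 1e-12)
  # arithmetic of the headline quantities
  expect_equal(0.02 / 0.005, 4)
  pr <- prof[1, ]
  expect_equal(pr$ear_pct, 100 * (pr$ar - pr$basis_ar))
})

test_that("zero basis risk makes relative risk undefined, not infinite", {
  rt <- data.frame(id = 1:2, disease = "d", horizon = 3, ar = c(0.2, 0))
  basis <- data.frame(disease = "d", age_group = factor(c("40-49", "50-59")),
                      horizon = 3, basis_ar = c(0, 0.1), n = c(1, 1))
  prof <- relative_and_excess(rt, basis, age = c(45, 55))
  expect_true(is.na(prof$rar[prof$id == 1]))
  expect_equal(prof$rar[prof$id == 2], 0)
})

test_that("quantile strata reproduce the 33/50/66 semantics", {
  set.seed(72)
  n <- 10000
  rt <- data.frame(id = seq_len(n), disease = "d", horizon = 5,
                   ar = runif(n))
  strata <- risk_strata(rt, by_age = FALSE)
  expect_true(strata$low_upper <= strata$average_mid)
  expect_true(strata$average_mid <= strata$high_lower)
  # the printed-quantile property: share at or below the low bound is 33%
  expect_lt(abs(mean(rt$ar <= strata$low_upper) - 0.33), 1 / n + 1e-3)
  lab <- stratify(rt, strata)
  prop <- prop.table(table(lab$stratum))
  expect_lt(abs(prop[["low"]] - 0.33), 0.02)
  expect_lt(abs(prop[["average"]] - 0.33), 0.02)
  expect_lt(abs(prop[["high"]] - 0.34), 0.02)
  # boundary value is labeled low (inclusive downward)
  rt2 <- data.frame(id = 1, disease = "d", horizon = 5,
                    ar = strata$low_upper)
  expect_equal(as.character(stratify(rt2, strata)$stratum), "low")
})

test_that("identical risks collapse the strata to a single average group", {
  rt <- data.frame(id = 1:50, disease = "d", horizon = 5, ar = 0.07)
  strata <- risk_strata(rt, by_age = FALSE)
  lab <- stratify(rt, strata)
  expect_true(all(lab$stratum == "average"))
})

test_that("disease ranking is descending with documented tie-breaks", {
  rt <- data.frame(id = rep(1, 3), disease = c("a", "b", "c"), horizon = 5,
                   ar = c(0.3, 0.1, 0.2))
  rk <- rank_diseases(rt, 5)
  expect_equal(rk$rank[match(c("a", "b", "c"), rk$disease)], c(1, 3, 2))
  # invariant to input row order
  rk2 <- rank_diseases(rt[c(3, 1, 2), ], 5)
  expect_equal(rk2, rk)
  # ties broken by disease name
  rt3 <- data.frame(id = 1, disease = c("z", "m"), horizon = 5,
                    ar = c(0.2, 0.2))
  rk3 <- rank_diseases(rt3, 5)
  expect_equal(rk3$disease[rk3$rank == 1], "m")
  rk1 <- rank_diseases(rt[1, ], 5)
  expect_equal(rk1$rank, 1)
})
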