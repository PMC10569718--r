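test_that("negative log partial likelihood matches hand-computed toys", {
  ctx <- cox_context(toy2())
  # beta = 0: sum of log risk-set sizes, log 2 + log 1
  expect_equal(cox_nll(0, ctx), log(2))
  # beta = 1: -[1 - log(e + 1)] - [0 - log 1]
  expect_equal(cox_nll(1, ctx), -(1 - log(exp(1) + 1)), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:20) {
    tk <- random_task(25, 3)
    ctx <- cox_context(tk)
    rs <- build_risk_sets(tk)
    # beta = 0 with ties: each of the d_i events contributes log |R(T_i)|
    expected <- sum(rs$n_events * log(lengths(rs$risk_sets)))
    expect_equal(cox_nll(numeric(3), ctx), expected, tolerance = 1e-12)
  }
})

test_that("gradient equals event covariate minus risk-set weighted mean", {
  ctx <- cox_context(toy2())
  expect_equal(cox_gradient(0, ctx), -0.5, ignore_attr = TRUE)  # -(1 - 1/2)

  set.seed(6)
  tk <- random_task(20, 3)
  ctx <- cox_context(tk)
  rs <- build_risk_sets(tk)
  # at beta = 0 the weights are equal: unweighted risk-set means
  manual <- -colSums(do.call(rbind, lapply(seq_along(rs$event_times), function(i) {
    mu <- colMeans(tk$X[rs$risk_sets[[i]], , drop = FALSE])
    colSums(tk$X[rs$event_members[[i]], , drop = FALSE] -
              matrix(mu, rs$n_events[i], tk$p, byrow = TRUE))
  })))
  expect_equal(cox_gradient(numeric(3), ctx), -(-manual), tolerance = 1e-10)
})

test_that("gradient and Hessian agree with central finite differences", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(10:50, 1); p <- sample(2:8, 1)
    tk <- random_task(n, p, tie_prob = rep %% 2)
    ctx <- cox_context(tk)
    b <- rnorm(p) * 0.5
    g <- cox_gradient(b, ctx)
    gfd <- fd_gradient(function(x) cox_nll(x, ctx), b)
    expect_lt(max(abs(g - gfd) / pmax(1, abs(gfd))), 1e-6)
    H <- cox_hessian(b, ctx)
    Hfd <- sapply(seq_len(p), function(j) {
      e <- numeric(p); e[j] <- 1e-5
      (cox_gradient(b + e, ctx) - cox_gradient(b - e, ctx)) / 2e-5
    })
    expect_lt(max(abs(H - Hfd)), 1e-5)
    expect_gt(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("Hessian of a single-subject risk set is zero (point-mass variance)", {
  t1 <- survival_task("one", matrix(2.5, 1, 1, dimnames = list(NULL, "x")),
                      3, 1)
  expect_equal(cox_hessian(0.7, cox_context(t1)), matrix(0, 1, 1),
               ignore_attr = TRUE)
})

test_that("partial likelihood is convex along random line segments", {
  set.seed(12)
  for (rep in 1:10) {
    tk <- random_task(30, 4)
    ctx <- cox_context(tk)
    b0 <- rnorm(4); d <- rnorm(4)
    vals <- vapply(seq(-1, 1, length.out = 41),
                   function(a) cox_nll(b0 + a * d, ctx), numeric(1))
    # convexity: second differences nonnegative (up to rounding)
    expect_gt(min(diff(diff(vals))), -1e-8)
  }
})

test_that("Breslow baseline at beta = 0 is the Nelson-Aalen estimator", {
  ctx <- cox_context(toy2())
  bb <- breslow_baseline(0, ctx)
  expect_equal(bb$cumhaz, c(0.5, 1.5))   # 1/2 then +1/1

  set.seed(13)
  tk <- random_task(40, 2)
  tk$time <- tk$time + runif(40, 0, 1e-6)    # break ties
  bb <- breslow_baseline(numeric(2), cox_context(tk))
  na_inc <- vapply(bb$event_times,
                   function(tt) 1 / sum(tk$time >= tt), numeric(1))
  expect_equal(bb$cumhaz, cumsum(na_inc), tolerance = 1e-12)
})

test_that("baseline incidence tracks Kaplan-Meier at n = 1000", {
  set.seed(14)
  n <- 1000
  tk <- survival_task("km", matrix(rnorm(n), n, 1, dimnames = list(NULL, "x")),
                      rexp(n, 0.3) + 1e-4, rbinom(n, 1, 0.7))
  bb <- breslow_baseline(0, cox_context(tk))
  km <- survival::survfit(survival::Surv(tk$time, tk$event) ~ 1)
  horizon <- quantile(tk$time, 0.8)
  inc_breslow <- 1 - exp(-baseline_cumhaz(bb, horizon))
  inc_km <- 1 - summary(km, times = horizon)$surv
  expect_lt(abs(inc_breslow - inc_km), 0.05)
})

test_that("absolute risk is a probability, monotone in horizon and risk score", {
  set.seed(15)
  tk <- random_task(60, 3, censor = 0.2)
  ctx <- cox_context(tk)
  beta <- fit_cox_newton(tk)$beta
  bb <- breslow_baseline(beta, ctx)
  horizons <- seq(0.2, max(tk$time), length.out = 8)
  ar <- sapply(horizons, function(h) absolute_risk(tk$X, beta, bb, h))
  expect_true(all(ar >= 0 & ar <= 1))
  expect_true(all(apply(ar, 1, function(r) all(diff(r) >= -1e-12))))
  # monotone in the linear predictor: scale one subject's x along beta
  x0 <- colMeans(tk$X)
  grid <- sapply(seq(-2, 2, 0.5), function(s) {
    absolute_risk(x0 + s * beta / sqrt(sum(beta^2)), beta, bb, horizons[4])
  })
  expect_true(all(diff(grid) >= -1e-12))
  # baseline subject: AR = 1 - S0; zero hazard horizon before first event
  expect_equal(absolute_risk(numeric(3), beta, bb, horizons[4]),
               1 - exp(-baseline_cumhaz(bb, horizons[4])))
  expect_equal(absolute_risk(numeric(3), beta, bb,
                             min(bb$event_times) / 2), 0)
  expect_warning(absolute_risk(x0, beta, bb, max(tk$time) + 1),
                 "beyond last observed time")
})
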