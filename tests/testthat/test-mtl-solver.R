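test_that("L2,1 norm: row norms summed; single column reduces to L1", {
  expect_equal(l21_norm(matrix(0, 4, 3)), 0)
  expect_equal(l21_norm(rbind(c(3, 4), c(0, 0))), 5)
  b <- c(1.5, -2, 0, 0.3)
  expect_equal(l21_norm(matrix(b, ncol = 1)), sum(abs(b)))
})

test_that("prox_l21 closed form matches numerical minimization per row", {
  G <- rbind(c(3, 4), c(0.1, 0.1))
  expect_equal(prox_l21(G, 0), G)                  # identity at zero threshold
  expect_equal(prox_l21(G, 10)[2, ], c(0, 0))      # small row zeroed

  set.seed(31)
  for (rep in 1:30) {
    G <- matrix(rnorm(18), 6, 3)
    for (tau in c(0, 0.05, 0.5, 1.5, 5)) {
      P <- prox_l21(G, tau)
      O <- t(apply(G, 1, prox_row_oracle, tau = tau))
      expect_lt(max(abs(P - O)), 1e-8)
      # rows are zero exactly when the row norm is below the threshold
      expect_identical(rowSums(P^2) == 0, sqrt(rowSums(G^2)) <= tau)
    }
  }
})

test_that("joint loss sums per-task NLL normalized by sample size", {
  set.seed(32)
  tasks <- list(random_task(20, 3, "a"), random_task(35, 3, "b"))
  ds <- multitask_dataset(tasks)
  B <- matrix(rnorm(6), 3, 2)
  manual <- sum(vapply(1:2, function(k) {
    cox_nll(B[, k], cox_context(tasks[[k]])) / tasks[[k]]$n
  }, numeric(1)))
  expect_equal(joint_loss(B, ds), manual, tolerance = 1e-12)
  # K = 1 reduction
  d1 <- multitask_dataset(tasks[1])
  expect_equal(joint_loss(B[, 1, drop = FALSE], d1),
               cox_nll(B[, 1], cox_context(tasks[[1]])) / tasks[[1]]$n)
})

test_that("lambda_max anchors the path: stationarity of the zero solution", {
  set.seed(33)
  sim <- simulate_tasks(sim_config(K = 2, P = 8, support = 3, n = 150,
                                   seed = 33))
  ds <- sim$dataset
  lm_ <- lambda_max(ds)
  expect_true(all(mtl_cox(ds, 1.01 * lm_, baselines = FALSE)$B == 0))
  f <- mtl_cox(ds, 0.5 * lm_, baselines = FALSE)
  expect_gt(sum(sqrt(rowSums(f$B^2)) > 1e-8), 0)
  # an all-zero feature column contributes a zero gradient row
  for (k in seq_len(ds$K)) ds$tasks[[k]]$X[, 8] <- 0
  g0 <- mtlcox:::`.joint_loss_grad`(matrix(0, 8, 2),
                                    mtlcox:::mtl_contexts(ds))$gradient
  expect_equal(g0[8, ], c(0, 0))
})

test_that("K=1 unpenalized fit matches Newton Cox; penalized matches glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(34)
  sim <- simulate_tasks(sim_config(K = 1, P = 6, support = 3, n = 300,
                                   seed = 34))
  t1 <- sim$dataset$tasks[[1]]
  d1 <- multitask_dataset(list(t1))
  fit0 <- mtl_cox(d1, 0, control = mtl_control(tol_obj = 1e-10, tol_B = 1e-9),
                  baselines = FALSE)
  nw <- fit_cox_newton(t1)
  expect_lt(max(abs(fit0$B[, 1] - nw$beta)), 1e-4)

  lams <- lambda_path(lambda_max(d1), n_lambda = 8)
  g <- glmnet::glmnet(t1$X, survival::Surv(t1$time, t1$event),
                      family = "cox", lambda = lams, standardize = FALSE,
                      thresh = 1e-13)
  fits <- mtl_cox_path(d1, lams,
                       control = mtl_control(tol_obj = 1e-9, tol_B = 1e-8))
  for (i in seq_along(lams)) {
    expect_lt(max(abs(fits[[i]]$B[, 1] - as.numeric(g$beta[, i]))), 1e-3)
  }
})

test_that("objective history is nonincreasing and zero rows are shared", {
  set.seed(35)
  sim <- simulate_tasks(sim_config(K = 3, P = 12, support = 4, n = 200,
                                   seed = 35))
  f <- mtl_cox(sim$dataset, 0.3 * lambda_max(sim$dataset), baselines = FALSE)
  expect_true(all(diff(f$objective) <= 1e-10))
  # row sparsity is a row property: a zeroed feature is zero in every task
  rn <- sqrt(rowSums(f$B^2))
  for (p in which(rn <= 1e-8)) expect_equal(f$B[p, ], rep(0, 3),
                                            ignore_attr = TRUE)
  expect_gt(sum(rn <= 1e-8), 0)
  expect_gt(sum(rn > 1e-8), 0)
})

test_that("moderate penalties recover exact zero rows off the true support", {
  sim <- simulate_tasks(sim_config(K = 3, P = 20, support = 5, n = 400,
                                   seed = 36))
  f <- mtl_cox(sim$dataset, 0.25 * lambda_max(sim$dataset), baselines = FALSE)
  off <- setdiff(seq_len(20), seq_len(5))
  expect_true(any(rowSums(f$B[off, ]^2) == 0))
  expect_true(all(rowSums(f$B[seq_len(5), ]^2) > 0))
})

test_that("fixed-step proximal gradient obeys the O(1/j) rate envelope", {
  set.seed(37)
  ds <- simulate_tasks(sim_config(K = 2, P = 6, support = 2, n = 100,
                                  seed = 37))$dataset
  lam <- 0.4 * lambda_max(ds)
  tight <- mtl_cox(ds, lam, control = mtl_control(max_iter = 50000,
                                                  tol_obj = 1e-14,
                                                  tol_B = 1e-13),
                   baselines = FALSE)
  fstar <- tight$objective[length(tight$objective)]
  gam <- 2 * mtl_cox(ds, lam, baselines = FALSE)$gamma  # safely above L
  fx <- suppressWarnings(
    mtl_cox(ds, lam, control = mtl_control(max_iter = 200, tol_obj = 0,
                                           tol_B = 0, gamma0 = gam,
                                           accelerate = FALSE,
                                           line_search = FALSE),
            baselines = FALSE))
  j <- seq_along(fx$objective[-1])
  envelope <- sum(tight$B^2) * gam / (2 * j)   # ||B(0)-B*||^2 / (2 t j), B(0)=0
  expect_true(all(fx$objective[-1] - fstar <= envelope + 1e-12))
})

test_that("cross-validated penalty selection responds to signal strength", {
  # degenerate one-point path returns that penalty
  sim <- simulate_tasks(sim_config(K = 2, P = 6, support = 2, n = 120,
                                   seed = 38))
  set.seed(381)
  cv1 <- cv_mtl_cox(sim$dataset, n_lambda = 1, nfolds = 3)
  expect_equal(cv1$lambda_opt, lambda_max(sim$dataset))

  # strong signal: selected penalty below the anchor, cv concordance > 0.6
  sim2 <- simulate_tasks(sim_config(K = 2, P = 10, support = 4, n = 300,
                                    seed = 39))
  set.seed(391)
  cv2 <- cv_mtl_cox(sim2$dataset, n_lambda = 20)
  expect_lt(cv2$lambda_opt, lambda_max(sim2$dataset))
  expect_gt(max(cv2$cv_cindex), 0.6)

  # pure noise: the selected model is (near-)empty in most seeds
  empty <- vapply(1:10, function(s) {
    simn <- simulate_tasks(sim_config(K = 2, P = 10, support = 0, n = 120,
                                      censoring = 0.2, seed = 400 + s))
    set.seed(500 + s)
    cv <- cv_mtl_cox(simn$dataset, n_lambda = 15, nfolds = 3)
    sum(sqrt(rowSums(cv$fit$B^2)) > 1e-8) <= 2
  }, logical(1))
  expect_gte(sum(empty), 8)
})

test_that("relaxed refit keeps the support and removes shrinkage bias", {
  sim <- simulate_tasks(sim_config(K = 2, P = 10, support = 3, n = 500,
                                   seed = 40))
  lam <- 0.3 * lambda_max(sim$dataset)
  pen <- mtl_cox(sim$dataset, lam)
  rel <- relax_fit(pen, sim$dataset)
  rn_pen <- sqrt(rowSums(pen$B^2)) > 1e-8
  rn_rel <- sqrt(rowSums(rel$B^2)) > 1e-8
  expect_identical(rn_pen, rn_rel)
  act <- which(rn_pen)
  # the penalized estimate is shrunk toward zero relative to the refit
  expect_gt(sum(abs(rel$B[act, ])), sum(abs(pen$B[act, ])))
})
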