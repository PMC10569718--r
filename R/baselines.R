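#' Unpenalized Cox regression by Newton--Raphson
#'
#' Maximizes the Breslow partial likelihood using the analytic gradient
#' and Hessian, with step-halving and a small ridge jitter when the
#' Hessian is numerically singular.  Coefficients are capped in magnitude
#' when the likelihood is monotone (separation).
#'
#' @param task a \code{survival_task}.
#' @param max_iter Newton iteration cap.
#' @param tol convergence threshold on the gradient max-norm.
#' @param beta_cap magnitude cap flagging separation.
#' @return Object of class \code{"cox_newton_fit"}: list with \code{beta}
#'   (named), \code{vcov} (inverse Hessian), \code{nll}, \code{converged},
#'   \code{iterations}, and \code{baseline} (Breslow hazard at the
#'   solution).
#' @export
fit_cox_newton <- function(task, max_iter = 50, tol = 1e-8, beta_cap = 20) {
  ctx <- cox_context(task)
  p <- task$p
  beta <- numeric(p)
  nll <- cox_nll(beta, ctx)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- cox_gradient(beta, ctx)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- cox_hessian(beta, ctx)
    step <- tryCatch(solve(H, g),
                     error = function(e) solve(H + diag(1e-8, p), g))
    # step-halving until the objective decreases
    alpha <- 1
    repeat {
      beta_new <- beta - alpha * step
      nll_new <- tryCatch(cox_nll(beta_new, ctx), error = function(e) Inf)
      if (nll_new <= nll + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- beta_new
    nll <- nll_new
    if (any(abs(beta) > beta_cap)) {
      warning(sprintf("task '%s': coefficient magnitude exceeds %g; likely separation, capping",
                      task$name, beta_cap))
      beta <- pmin(pmax(beta, -beta_cap), beta_cap)
      nll <- cox_nll(beta, ctx)
      break
    }
  }
  if (!converged && max(abs(cox_gradient(beta, ctx))) >= 1e-4) {
    warning(sprintf("fit_cox_newton: not converged for task '%s'", task$name))
  }
  H <- cox_hessian(beta, ctx)
  vc <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-8, p)))
  names(beta) <- colnames(task$X)
  structure(
    list(beta = beta, vcov = vc, nll = nll, converged = converged,
         iterations = it, baseline = breslow_baseline(beta, ctx),
         task_name = task$name),
    class = "cox_newton_fit")
}

#' L1-penalized Cox regression (Cox-LASSO)
#'
#' Solves the Lagrangian form \eqn{\mathrm{NLL}(\beta)/N +
#' \lambda\sum_p|\beta_p|} — equivalent along the path to constraining
#' \eqn{\sum_p|\beta_p| \le s} — by the same proximal gradient solver as
#' the multitask model with a single task, where the L2,1 penalty
#' coincides with the L1 norm.
#'
#' @param task a \code{survival_task}.
#' @param penalty nonnegative L1 penalty \eqn{\lambda}.
#' @param control solver control (see \code{\link{mtl_control}}).
#' @return Object of class \code{"cox_lasso_fit"}: list with \code{beta},
#'   \code{penalty}, \code{converged}, \code{baseline}.
#' @export
fit_cox_lasso <- function(task, penalty, control = mtl_control()) {
  ds <- multitask_dataset(list(task))
  fit <- mtl_cox(ds, penalty, control = control, baselines = TRUE)
  structure(
    list(beta = stats::setNames(fit$B[, 1], rownames(fit$B)),
         penalty = penalty, converged = fit$converged,
         baseline = fit$baselines[[1]], task_name = task$name),
    class = "cox_lasso_fit")
}

#' Cross-validated Cox-LASSO over a geometric penalty path
#'
#' Mirrors the multitask selection protocol on one task: geometric grid
#' anchored at the single-task \eqn{\lambda_{max}}, k-fold
#' event-stratified cross-validation, penalty chosen by mean validation
#' concordance (ties toward the larger penalty).
#'
#' @inheritParams fit_cox_lasso
#' @param n_lambda,min_ratio,first_scale path settings.
#' @param nfolds cross-validation folds.
#' @return A \code{cox_lasso_fit} refit on all data at the selected
#'   penalty, with \code{cv} attached.
#' @export
cv_cox_lasso <- function(task, n_lambda = 50, min_ratio = 0.01,
                         first_scale = 1, nfolds = 5,
                         control = mtl_control(max_iter = 2000,
                                               tol_obj = 1e-5, tol_B = 1e-4)) {
  ds <- multitask_dataset(list(task))
  cv <- cv_mtl_cox(ds, n_lambda = n_lambda, min_ratio = min_ratio,
                   first_scale = first_scale, nfolds = nfolds,
                   control = control)
  out <- fit_cox_lasso(task, cv$lambda_opt)
  out$cv <- list(lambda = cv$lambda, cv_cindex = cv$cv_cindex,
                 lambda_opt = cv$lambda_opt)
  out
}

#' Weibull proportional-hazards regression
#'
#' Parametric baseline \eqn{h_0(t) = \nu\gamma t^{\nu-1}} with hazard
#' \eqn{h(t|x) = h_0(t) e^{\theta x}}.  Estimated by maximum likelihood
#' through \code{survival::survreg} (accelerated-failure-time
#' parameterization) and converted to the proportional-hazards scale:
#' shape \eqn{\nu = 1/\sigma}, \eqn{\theta = -b_{AFT}/\sigma}, baseline
#' rate \eqn{\gamma = e^{-\mu/\sigma}}.
#'
#' @param task a \code{survival_task}.
#' @return Object of class \code{"weibull_ph_fit"}: list with
#'   \code{shape}, \code{rate} (baseline scale \eqn{\gamma}),
#'   \code{coefficients} (\eqn{\theta}, hazard-ratio scale),
#'   \code{intercept} (AFT \eqn{\mu}), \code{sigma}, \code{converged},
#'   and the underlying \code{survreg} fit.
#' @export
fit_weibull_ph <- function(task) {
  df <- data.frame(.time = task$time, .event = task$event,
                   task$X, check.names = TRUE)
  xn <- colnames(df)[-(1:2)]
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(xn, collapse = " + ")))
  sr <- survival::survreg(fml, data = df, dist = "weibull")
  sigma <- sr$scale
  mu <- unname(stats::coef(sr)[1])
  b_aft <- stats::coef(sr)[-1]
  theta <- stats::setNames(-b_aft / sigma, colnames(task$X))
  structure(
    list(shape = 1 / sigma, rate = exp(-mu / sigma), coefficients = theta,
         intercept = mu, sigma = sigma,
         converged = is.null(sr$fail) || !sr$fail, survreg = sr,
         task_name = task$name),
    class = "weibull_ph_fit")
}

#' Absolute risk under a fitted Weibull proportional-hazards model
#'
#' \eqn{AR = 1 - \exp\{-\gamma h^{\nu} e^{\theta x}\}} at horizon \eqn{h}.
#'
#' @param fit a \code{weibull_ph_fit}.
#' @param x feature vector or matrix (subjects in rows).
#' @param horizon positive horizon in years.
#' @return Absolute risk(s) in \eqn{[0,1]}.
#' @export
weibull_absolute_risk <- function(fit, x, horizon) {
  stopifnot(horizon > 0)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  H0 <- fit$rate * horizon^fit$shape
  drop(1 - exp(-H0 * exp(x %*% fit$coefficients)))
}
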