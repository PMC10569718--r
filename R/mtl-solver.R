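#' L2,1 norm of a coefficient matrix
#'
#' Sum over rows of the Euclidean row norm,
#' \eqn{\|B\|_{2,1} = \sum_p \|\beta^p\|_2}.  Rows index features, columns
#' index tasks; the penalty drives entire rows to zero so that feature
#' selection is shared across tasks.  With a single column it reduces to
#' the L1 norm.
#'
#' @param B numeric matrix (features x tasks).
#' @return The scalar L2,1 norm.
#' @export
l21_norm <- function(B) {
  sum(sqrt(rowSums(B^2)))
}

#' Proximal operator of the L2,1 norm
#'
#' Solves \eqn{\arg\min_B \frac12\|B-G\|_2^2 + \tau\|B\|_{2,1}} in closed
#' form: the problem separates over rows and each row is group
#' soft-thresholded, \eqn{B_p = G_p \max(0, 1 - \tau/\|G_p\|_2)}.  Rows
#' with \eqn{\|G_p\|_2 \le \tau} are set exactly to zero.
#'
#' @param G numeric matrix (features x tasks).
#' @param threshold nonnegative scalar \eqn{\tau} (penalty times step size).
#' @return Matrix of the same shape as \code{G}.
#' @export
prox_l21 <- function(G, threshold) {
  stopifnot(threshold >= 0)
  if (threshold == 0) return(G)
  rn <- sqrt(rowSums(G^2))
  shrink <- pmax(0, 1 - threshold / pmax(rn, .Machine$double.eps))
  G * shrink
}

# per-task likelihood contexts plus the task weights 1/N_k (or 1/events)
mtl_contexts <- function(dataset, normalization = c("subjects", "events")) {
  normalization <- match.arg(normalization)
  ctxs <- lapply(dataset$tasks, cox_context)
  wts <- unname(vapply(dataset$tasks, function(t) {
    if (normalization == "subjects") 1 / t$n else 1 / sum(t$event)
  }, numeric(1)))
  list(ctxs = ctxs, weights = wts, K = dataset$K, p = dataset$p,
       feature_names = dataset$registry$name,
       task_names = names(dataset$tasks))
}

#' Joint multitask Cox loss
#'
#' The smooth part of the objective:
#' \eqn{L(B) = \sum_k \mathrm{NLL}_k(\beta_k)/N_k}, each task's negative
#' log partial likelihood normalized by its sample size so that cohorts of
#' different sizes contribute comparably.
#'
#' @param B coefficient matrix (features x tasks).
#' @param dataset a \code{multitask_dataset}, or the context list produced
#'   internally.
#' @param normalization divide each task's loss by its subject count
#'   (default) or by its event count.
#' @return Scalar loss.
#' @export
joint_loss <- function(B, dataset,
                       normalization = c("subjects", "events")) {
  mc <- if (inherits(dataset, "multitask_dataset")) {
    mtl_contexts(dataset, match.arg(normalization))
  } else dataset
  val <- 0
  for (k in seq_len(mc$K)) {
    val <- val + mc$weights[k] * cox_nll(B[, k], mc$ctxs[[k]])
  }
  val
}

# value + gradient matrix of the joint smooth loss
.joint_loss_grad <- function(B, mc) {
  val <- 0
  Gr <- matrix(0, mc$p, mc$K)
  for (k in seq_len(mc$K)) {
    vg <- cox_nll_grad(B[, k], mc$ctxs[[k]])
    val <- val + mc$weights[k] * vg$value
    Gr[, k] <- mc$weights[k] * vg$gradient
  }
  list(value = val, gradient = Gr)
}

#' Smallest penalty for which the all-zero solution is optimal
#'
#' With \eqn{B=0}, zero is stationary iff every row of the smooth-loss
#' gradient has Euclidean norm at most \eqn{\lambda}; the maximum row norm
#' of \eqn{\nabla L(0)} therefore anchors the regularization path.
#'
#' @param dataset a \code{multitask_dataset}.
#' @param normalization see \code{\link{joint_loss}}.
#' @return Positive scalar \eqn{\lambda_{max}}.
#' @export
lambda_max <- function(dataset, normalization = c("subjects", "events")) {
  mc <- mtl_contexts(dataset, match.arg(normalization))
  g0 <- .joint_loss_grad(matrix(0, mc$p, mc$K), mc)$gradient
  max(sqrt(rowSums(g0^2)))
}

#' Geometric regularization path
#'
#' A decreasing geometric grid of \code{n_lambda} penalties from
#' \code{first_scale * lambda_max} down to \code{min_ratio} times the first
#' value.  Defaults (50, 0.01, 1) are the search-grid settings the method
#' is tuned with.
#'
#' @param lambda_max data-derived path anchor (see \code{\link{lambda_max}}).
#' @param n_lambda number of grid points.
#' @param min_ratio ratio of the smallest to the largest grid value.
#' @param first_scale multiplier applied to \code{lambda_max} for the first
#'   grid point.
#' @return Decreasing numeric vector of length \code{n_lambda}.
#' @export
lambda_path <- function(lambda_max, n_lambda = 50, min_ratio = 0.01,
                        first_scale = 1) {
  stopifnot(lambda_max > 0, n_lambda >= 1, min_ratio > 0, min_ratio <= 1)
  top <- first_scale * lambda_max
  if (n_lambda == 1) return(top)
  exp(seq(log(top), log(min_ratio * top), length.out = n_lambda))
}

#' Solver control parameters
#'
#' @param max_iter iteration cap.
#' @param tol_obj relative objective-change tolerance.
#' @param tol_B relative coefficient-change (Frobenius) tolerance.
#' @param gamma0 initial inverse step size (Lipschitz estimate).
#' @param accelerate use momentum extrapolation (FISTA); plain proximal
#'   gradient otherwise.
#' @param line_search backtracking on the inverse step (doubling until the
#'   quadratic majorization holds); if \code{FALSE}, \code{gamma0} is used
#'   as a fixed inverse step and must then dominate the gradient's
#'   Lipschitz constant.
#' @return A list of class \code{"mtl_control"}.
#' @export
mtl_control <- function(max_iter = 5000, tol_obj = 1e-6, tol_B = 1e-5,
                        gamma0 = 1, accelerate = TRUE, line_search = TRUE) {
  structure(list(max_iter = max_iter, tol_obj = tol_obj, tol_B = tol_B,
                 gamma0 = gamma0, accelerate = accelerate,
                 line_search = line_search),
            class = "mtl_control")
}

# one accepted proximal step from search point S: backtracks gamma until
# L(B_new) <= L(S) + <grad, B_new - S> + gamma/2 ||B_new - S||_F^2
.prox_step <- function(S, mc, lambda, gamma, control) {
  vg <- .joint_loss_grad(S, mc)
  repeat {
    B_new <- prox_l21(S - vg$gradient / gamma, lambda / gamma)
    if (!control$line_search) break
    dB <- B_new - S
    quad <- vg$value + sum(vg$gradient * dB) + gamma / 2 * sum(dB^2)
    L_new <- joint_loss(B_new, mc)
    if (L_new <= quad + 1e-12 * max(1, abs(quad))) break
    gamma <- 2 * gamma
  }
  list(B = B_new, gamma = gamma)
}

#' Fit the multitask Cox model at one penalty level
#'
#' Minimizes \eqn{\sum_k \mathrm{NLL}_k(\beta_k)/N_k + \lambda\|B\|_{2,1}}
#' by accelerated proximal gradient: at each iteration a search point is
#' extrapolated from the previous two iterates, a gradient step is taken,
#' and the L2,1 proximal operator is applied; the inverse step size is
#' found by backtracking (doubling until the quadratic majorization at the
#' search point holds).  If an extrapolated step would increase the
#' objective, the momentum is restarted so the recorded objective history
#' is nonincreasing.
#'
#' @param dataset a \code{multitask_dataset}.
#' @param lambda nonnegative penalty.
#' @param control a \code{\link{mtl_control}} list.
#' @param B0 optional warm-start coefficient matrix (defaults to zero).
#' @param normalization see \code{\link{joint_loss}}.
#' @param baselines compute per-task Breslow baseline hazards at the
#'   solution.
#' @return An object of class \code{"mtl_cox_fit"}: list with \code{B}
#'   (features x tasks, dimnames set), \code{lambda}, \code{objective}
#'   (history of accepted iterates), \code{converged}, \code{iterations},
#'   \code{gamma} (final inverse step), and \code{baselines} (named list of
#'   \code{baseline_hazard}, if requested).
#' @export
mtl_cox <- function(dataset, lambda, control = mtl_control(), B0 = NULL,
                    normalization = c("subjects", "events"),
                    baselines = TRUE) {
  stopifnot(lambda >= 0)
  mc <- if (inherits(dataset, "multitask_dataset")) {
    mtl_contexts(dataset, match.arg(normalization))
  } else dataset
  p <- mc$p; K <- mc$K
  B_cur <- if (is.null(B0)) matrix(0, p, K) else B0
  B_prev <- B_cur
  q <- 1
  gamma <- control$gamma0
  F_cur <- joint_loss(B_cur, mc) + lambda * l21_norm(B_cur)
  obj <- numeric(control$max_iter + 1)
  obj[1] <- F_cur
  converged <- FALSE
  j <- 0L
  while (j < control$max_iter) {
    j <- j + 1L
    if (control$accelerate) {
      q_new <- (1 + sqrt(1 + 4 * q^2)) / 2
      mom <- (q - 1) / q_new
      S <- B_cur + mom * (B_cur - B_prev)
    } else {
      q_new <- q
      S <- B_cur
    }
    st <- .prox_step(S, mc, lambda, gamma, control)
    F_new <- joint_loss(st$B, mc) + lambda * l21_norm(st$B)
    if (F_new > F_cur + 1e-12 * max(1, abs(F_cur)) && control$accelerate) {
      # momentum restart: retake the step from the current iterate
      q_new <- 1
      st <- .prox_step(B_cur, mc, lambda, st$gamma, control)
      F_new <- joint_loss(st$B, mc) + lambda * l21_norm(st$B)
    }
    gamma <- st$gamma
    if (F_new > F_cur + 1e-12 * max(1, abs(F_cur))) {
      # no descent direction left at this resolution: stop at best iterate
      converged <- TRUE
      j <- j - 1L
      break
    }
    dB_rel <- sqrt(sum((st$B - B_cur)^2)) / max(1, sqrt(sum(B_cur^2)))
    dF_rel <- (F_cur - F_new) / max(1, abs(F_cur))
    B_prev <- B_cur
    B_cur <- st$B
    q <- q_new
    F_cur <- F_new
    obj[j + 1] <- F_cur
    if (dF_rel < control$tol_obj || dB_rel < control$tol_B) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("mtl_cox did not converge in %d iterations (lambda=%.3g)",
                    control$max_iter, lambda))
  }
  dimnames(B_cur) <- list(mc$feature_names, mc$task_names)
  fit <- structure(
    list(B = B_cur, lambda = lambda, objective = obj[seq_len(j + 1)],
         converged = converged, iterations = j, gamma = gamma,
         task_names = mc$task_names, baselines = NULL),
    class = "mtl_cox_fit")
  if (baselines) {
    fit$baselines <- lapply(seq_len(K), function(k) {
      breslow_baseline(B_cur[, k], mc$ctxs[[k]])
    })
    names(fit$baselines) <- mc$task_names
  }
  fit
}

#' @export
print.mtl_cox_fit <- function(x, ...) {
  nz <- sum(sqrt(rowSums(x$B^2)) > 1e-8)
  cat(sprintf("<mtl_cox_fit: lambda=%.4g, %d/%d active feature rows, %d iterations%s>\n",
              x$lambda, nz, nrow(x$B), x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Fit the multitask Cox model along a penalty path with warm starts
#'
#' @param dataset a \code{multitask_dataset}.
#' @param lambdas decreasing penalty grid (see \code{\link{lambda_path}}).
#' @param control solver control.
#' @param normalization see \code{\link{joint_loss}}.
#' @return List of \code{mtl_cox_fit}, one per penalty, without baselines.
#' @export
mtl_cox_path <- function(dataset, lambdas, control = mtl_control(),
                         normalization = c("subjects", "events")) {
  mc <- if (inherits(dataset, "multitask_dataset")) {
    mtl_contexts(dataset, match.arg(normalization))
  } else dataset
  fits <- vector("list", length(lambdas))
  B0 <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- mtl_cox(mc, lambdas[i], control = control, B0 = B0,
                         baselines = FALSE)
    B0 <- fits[[i]]$B
  }
  fits
}

# event-stratified fold assignment for one task (events and censored
# subjects each spread evenly over folds)
.stratified_folds <- function(event, nfolds) {
  fold <- integer(length(event))
  for (grp in list(which(event == 1), which(event == 0))) {
    if (length(grp) == 0) next
    fold[sample(grp)] <- rep_len(seq_len(nfolds), length(grp))
  }
  fold
}

.subset_dataset <- function(dataset, keep) {
  tasks <- lapply(seq_len(dataset$K), function(k) {
    t <- dataset$tasks[[k]]
    idx <- keep[[k]]
    survival_task(t$name, t$X[idx, , drop = FALSE], t$time[idx],
                  t$event[idx], id = t$id[idx])
  })
  multitask_dataset(tasks, dataset$registry)
}

#' Debias a penalized multitask fit by unpenalized refit on its support
#'
#' The L2,1 point estimate is biased toward zero by design (group
#' shrinkage is what buys the row sparsity).  For coefficient reporting
#' the standard remedy is a relaxed fit: keep the selected rows and refit
#' each task by unpenalized Newton Cox restricted to those features,
#' leaving the discarded rows at exactly zero.  The support is unchanged.
#'
#' @param fit an \code{mtl_cox_fit}.
#' @param dataset the training \code{multitask_dataset}.
#' @param tol row-norm threshold defining the active set.
#' @return An \code{mtl_cox_fit} with debiased \code{B} and refreshed
#'   baselines; \code{relaxed = TRUE} is recorded.
#' @export
relax_fit <- function(fit, dataset, tol = 1e-8) {
  active <- which(sqrt(rowSums(fit$B^2)) > tol)
  B <- matrix(0, nrow(fit$B), ncol(fit$B), dimnames = dimnames(fit$B))
  for (k in seq_len(dataset$K)) {
    t <- dataset$tasks[[k]]
    if (length(active) > 0) {
      sub <- survival_task(t$name, t$X[, active, drop = FALSE],
                           t$time, t$event)
      B[active, k] <- suppressWarnings(fit_cox_newton(sub))$beta
    }
  }
  fit$B <- B
  fit$relaxed <- TRUE
  fit$baselines <- lapply(seq_len(dataset$K), function(k) {
    breslow_baseline(B[, k], cox_context(dataset$tasks[[k]]))
  })
  names(fit$baselines) <- fit$task_names
  fit
}

#' Select the penalty by k-fold cross-validated concordance
#'
#' Splits every task's subjects into event-stratified folds (one shared
#' fold structure per task), fits the penalty path on each training split
#' with warm starts, scores each held-out fold by the concordance index of
#' the linear predictor per task, and selects the penalty from the mean
#' validation concordance (averaged over tasks, then folds).  By default
#' the one-standard-error rule is applied: the largest penalty whose mean
#' concordance is within one fold standard error of the maximum.  The
#' concordance is invariant to rescaling each task's coefficients, so its
#' CV curve plateaus around the optimum; the parsimony rule resolves the
#' plateau toward sparser models and returns the empty model on pure
#' noise.  With \code{one_se = FALSE} the plain argmax is used (ties
#' toward the larger penalty).
#'
#' @param dataset a \code{multitask_dataset}.
#' @param n_lambda,min_ratio,first_scale path settings
#'   (see \code{\link{lambda_path}}); defaults 50, 0.01, 1.
#' @param nfolds number of folds (default 5).
#' @param control solver control (a looser default than
#'   \code{\link{mtl_cox}} is used for the inner path fits).
#' @param normalization see \code{\link{joint_loss}}.
#' @param relax debias the final fit by unpenalized refit on the selected
#'   rows (see \code{\link{relax_fit}}); off by default, so predictions
#'   use the penalized estimate.
#' @param one_se apply the one-standard-error parsimony rule (default).
#' @return An object of class \code{"cv_mtl_cox"}: list with
#'   \code{lambda} (grid), \code{cv_cindex} (mean per penalty),
#'   \code{cv_folds} (fold x penalty matrix), \code{lambda_opt},
#'   \code{fit} (final \code{mtl_cox_fit} on the full data at
#'   \code{lambda_opt}, with baselines), and \code{folds}.
#' @export
cv_mtl_cox <- function(dataset, n_lambda = 50, min_ratio = 0.01,
                       first_scale = 1, nfolds = 5,
                       control = mtl_control(max_iter = 2000, tol_obj = 1e-5,
                                             tol_B = 1e-4),
                       normalization = c("subjects", "events"),
                       relax = FALSE, one_se = TRUE) {
  normalization <- match.arg(normalization)
  lam_max <- lambda_max(dataset, normalization)
  lambdas <- lambda_path(lam_max, n_lambda, min_ratio, first_scale)
  folds <- lapply(dataset$tasks, function(t) {
    f <- .stratified_folds(t$event, nfolds)
    # every training split must retain events in every task
    while (any(vapply(seq_len(nfolds), function(ff) {
      sum(t$event[f != ff]) == 0
    }, logical(1)))) {
      f <- .stratified_folds(t$event, nfolds)
    }
    f
  })
  cvmat <- matrix(NA_real_, nfolds, length(lambdas))
  for (ff in seq_len(nfolds)) {
    train <- .subset_dataset(dataset, lapply(folds, function(f) which(f != ff)))
    val_idx <- lapply(folds, function(f) which(f == ff))
    fits <- mtl_cox_path(train, lambdas, control = control,
                         normalization = normalization)
    for (i in seq_along(lambdas)) {
      ci <- vapply(seq_len(dataset$K), function(k) {
        t <- dataset$tasks[[k]]
        idx <- val_idx[[k]]
        sc <- drop(t$X[idx, , drop = FALSE] %*% fits[[i]]$B[, k])
        c_index(sc, t$time[idx], t$event[idx], na_if_undefined = TRUE)
      }, numeric(1))
      cvmat[ff, i] <- mean(ci, na.rm = TRUE)
    }
  }
  cv_mean <- colMeans(cvmat, na.rm = TRUE)
  imax <- which.max(cv_mean)   # grid is decreasing: first max = largest lambda
  best <- if (one_se) {
    se <- stats::sd(cvmat[, imax]) / sqrt(nfolds)
    which(cv_mean >= cv_mean[imax] - se)[1]
  } else imax
  fit <- mtl_cox(dataset, lambdas[best],
                 control = mtl_control(max_iter = control$max_iter * 2),
                 normalization = normalization, baselines = TRUE)
  if (relax) fit <- relax_fit(fit, dataset)
  structure(
    list(lambda = lambdas, cv_cindex = cv_mean, cv_folds = cvmat,
         lambda_opt = lambdas[best], fit = fit, folds = folds),
    class = "cv_mtl_cox")
}

#' @export
print.cv_mtl_cox <- function(x, ...) {
  cat(sprintf("<cv_mtl_cox: %d penalties, lambda_opt=%.4g (cv C-index %.3f)>\n",
              length(x$lambda), x$lambda_opt,
              x$cv_cindex[which.max(x$cv_cindex)]))
  print(x$fit)
  invisible(x)
}

#' Serialize a fitted multitask Cox model to a directory of text files
#'
#' Writes the coefficient table (feature x task), one baseline-hazard file
#' per task, the standardization parameters when present, and a metadata
#' file recording the penalty and solver diagnostics.
#'
#' @param fit an \code{mtl_cox_fit}.
#' @param dir output directory.
#' @param standardization optional \code{$standardization} of the training
#'   dataset.
#' @return Invisibly, \code{dir}.
#' @export
save_mtl_fit <- function(fit, dir, standardization = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(feature = rownames(fit$B), fit$B, check.names = FALSE),
    file.path(dir, "coefficients.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  if (!is.null(fit$baselines)) {
    for (nm in names(fit$baselines)) {
      write_baseline(fit$baselines[[nm]],
                     file.path(dir, paste0("baseline_", nm, ".csv")))
    }
  }
  if (!is.null(standardization) && standardization$scope == "pooled") {
    utils::write.table(
      data.frame(feature = names(standardization$center),
                 center = standardization$center,
                 scale = standardization$scale),
      file.path(dir, "standardization.csv"), sep = ",", row.names = FALSE,
      quote = FALSE)
  }
  meta <- c(lambda = fit$lambda, iterations = fit$iterations,
            converged = as.integer(fit$converged),
            final_objective = fit$objective[length(fit$objective)])
  utils::write.table(
    data.frame(key = names(meta), value = unname(meta)),
    file.path(dir, "metadata.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}
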