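#' Two-stage feature screen: univariate Cox then forward selection
#'
#' Stage 1 keeps features whose univariate Cox Wald p-value is below the
#' threshold; stage 2 runs forward selection among the survivors, adding
#' at each step the feature with the largest partial-likelihood
#' improvement while its likelihood-ratio entry p-value stays below the
#' threshold.  An optional pre-modelling utility; the union of per-task
#' selections is the usual model input.
#'
#' @param task a \code{survival_task}.
#' @param p_threshold entry threshold for both stages (default 0.05).
#' @return Character vector of selected feature names.  When nothing
#'   survives, all features are passed through with a warning.
#' @export
screen_features <- function(task, p_threshold = 0.05) {
  feat <- colnames(task$X)
  # stage 1: mono-factor (univariate) Wald tests
  p_uni <- vapply(feat, function(f) {
    t1 <- survival_task(task$name, task$X[, f, drop = FALSE],
                        task$time, task$event)
    fit <- suppressWarnings(fit_cox_newton(t1))
    se <- sqrt(diag(fit$vcov))
    2 * stats::pnorm(-abs(fit$beta / se))
  }, numeric(1))
  stage1 <- feat[p_uni < p_threshold]
  if (length(stage1) == 0) {
    warning("no feature passed the univariate screen; passing all features through")
    return(feat)
  }
  # stage 2: forward selection by partial-likelihood ratio
  selected <- character(0)
  remaining <- stage1
  ctx_nll <- function(cols) {
    t1 <- survival_task(task$name, task$X[, cols, drop = FALSE],
                        task$time, task$event)
    suppressWarnings(fit_cox_newton(t1))$nll
  }
  # null-model NLL: beta = 0 on a dummy column gives the intercept-free loss
  nll_cur <- cox_nll(0, cox_context(survival_task(task$name,
                       matrix(0, task$n, 1, dimnames = list(NULL, ".null")),
                       task$time, task$event)))
  repeat {
    if (length(remaining) == 0) break
    cand <- vapply(remaining, function(f) ctx_nll(c(selected, f)), numeric(1))
    lrt <- 2 * (nll_cur - cand)           # chi^2_1 improvement per entry
    pvals <- stats::pchisq(pmax(lrt, 0), df = 1, lower.tail = FALSE)
    best <- which.min(pvals)
    if (pvals[best] >= p_threshold) break
    selected <- c(selected, remaining[best])
    nll_cur <- cand[best]
    remaining <- remaining[-best]
  }
  if (length(selected) == 0) {
    warning("forward selection kept no feature; returning stage-1 survivors")
    return(stage1)
  }
  selected
}

# evaluate one fitted method on a validation split of one task
.eval_method <- function(score, ar, time, event, horizon) {
  ci <- c_index(score, time, event, na_if_undefined = TRUE)
  bin <- binarize_at_horizon(time, event, horizon)
  roc <- roc_auc(ar, bin$labels)
  data.frame(metric = c("c_index", "auc", "sensitivity", "specificity",
                        "youden"),
             value = c(as.numeric(ci), roc$auc, roc$sensitivity,
                       roc$specificity, roc$youden))
}

#' Run the full cross-validated benchmarking experiment
#'
#' Event-stratified k-fold split shared by all methods; on each training
#' split the multitask model selects its penalty by nested
#' cross-validation (as does the Cox-LASSO, per task), the unpenalized
#' Cox and Weibull models are fit directly; every method is scored on the
#' held-out fold (concordance of the linear predictor; AUC, sensitivity,
#' specificity and Youden index of the absolute risk dichotomized at the
#' evaluation horizon with the Youden-optimal cutoff).  Paired Wilcoxon
#' signed-rank tests compare the multitask model against each competitor
#' over disease x fold pairs.
#'
#' @param dataset a \code{multitask_dataset}.
#' @param methods subset of \code{c("mtl_cox", "cox", "cox_lasso",
#'   "weibull")}.
#' @param nfolds outer folds (default 5).
#' @param inner_nfolds folds of the nested penalty selection.
#' @param n_lambda,min_ratio,first_scale penalty path settings
#'   (defaults 50, 0.01, 1).
#' @param horizon_eval horizon (years) for the binary conversion
#'   (default 5).
#' @param seed integer seed controlling the fold split.
#' @param out_dir optional directory; when given, the metrics table,
#'   comparison table, coefficient table and run metadata are written as
#'   delimited text.
#' @param control solver control for the path fits.
#' @return List of class \code{"mtl_experiment"}: \code{metrics} (disease
#'   x method x fold x metric), \code{comparisons} (Wilcoxon table),
#'   \code{folds}, \code{final_fit} (cross-validated multitask fit on all
#'   data), \code{config}.
#' @export
run_experiment <- function(dataset,
                           methods = c("mtl_cox", "cox", "cox_lasso", "weibull"),
                           nfolds = 5, inner_nfolds = 5, n_lambda = 50,
                           min_ratio = 0.01, first_scale = 1,
                           horizon_eval = 5, seed = 1, out_dir = NULL,
                           control = mtl_control(max_iter = 2000,
                                                 tol_obj = 1e-5, tol_B = 1e-4)) {
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  folds <- lapply(dataset$tasks, function(t) {
    f <- .stratified_folds(t$event, nfolds)
    while (any(vapply(seq_len(nfolds), function(ff) {
      sum(t$event[f != ff]) == 0 || sum(t$event[f == ff]) == 0
    }, logical(1)))) {
      f <- .stratified_folds(t$event, nfolds)
    }
    f
  })
  task_names <- names(dataset$tasks)
  rows <- list()
  for (ff in seq_len(nfolds)) {
    train_idx <- lapply(folds, function(f) which(f != ff))
    val_idx <- lapply(folds, function(f) which(f == ff))
    train <- .subset_dataset(dataset, train_idx)

    fits <- list()
    if ("mtl_cox" %in% methods) {
      fits$mtl_cox <- cv_mtl_cox(train, n_lambda = n_lambda,
                                 min_ratio = min_ratio,
                                 first_scale = first_scale,
                                 nfolds = inner_nfolds, control = control)$fit
    }
    for (k in seq_len(dataset$K)) {
      t_tr <- train$tasks[[k]]
      t_full <- dataset$tasks[[k]]
      idx <- val_idx[[k]]
      Xv <- t_full$X[idx, , drop = FALSE]
      tv <- t_full$time[idx]; evv <- t_full$event[idx]

      score_ar <- list()
      if ("mtl_cox" %in% methods) {
        fit <- fits$mtl_cox
        score_ar$mtl_cox <- list(
          score = drop(Xv %*% fit$B[, k]),
          ar = absolute_risk(Xv, fit$B[, k], fit$baselines[[k]], horizon_eval))
      }
      if ("cox" %in% methods) {
        fit <- suppressWarnings(fit_cox_newton(t_tr))
        score_ar$cox <- list(
          score = drop(Xv %*% fit$beta),
          ar = absolute_risk(Xv, fit$beta, fit$baseline, horizon_eval))
      }
      if ("cox_lasso" %in% methods) {
        fit <- cv_cox_lasso(t_tr, n_lambda = n_lambda, min_ratio = min_ratio,
                            first_scale = first_scale, nfolds = inner_nfolds,
                            control = control)
        score_ar$cox_lasso <- list(
          score = drop(Xv %*% fit$beta),
          ar = absolute_risk(Xv, fit$beta, fit$baseline, horizon_eval))
      }
      if ("weibull" %in% methods) {
        fit <- fit_weibull_ph(t_tr)
        score_ar$weibull <- list(
          score = drop(Xv %*% fit$coefficients),
          ar = weibull_absolute_risk(fit, Xv, horizon_eval))
      }
      for (m in names(score_ar)) {
        ev_tab <- suppressWarnings(
          .eval_method(score_ar[[m]]$score, score_ar[[m]]$ar, tv, evv,
                       horizon_eval))
        ev_tab$disease <- task_names[k]
        ev_tab$method <- m
        ev_tab$fold <- ff
        rows[[length(rows) + 1]] <- ev_tab
      }
    }
  }
  metrics <- do.call(rbind, rows)[, c("disease", "method", "fold",
                                      "metric", "value")]

  comparisons <- NULL
  if ("mtl_cox" %in% methods && length(methods) > 1) {
    comp_rows <- list()
    for (m in setdiff(methods, "mtl_cox")) {
      for (met in unique(metrics$metric)) {
        a <- metrics[metrics$method == "mtl_cox" & metrics$metric == met, ]
        b <- metrics[metrics$method == m & metrics$metric == met, ]
        key <- paste(a$disease, a$fold)
        b <- b[match(key, paste(b$disease, b$fold)), ]
        w <- paired_wilcoxon(a$value, b$value)
        comp_rows[[length(comp_rows) + 1]] <- data.frame(
          metric = met, method_a = "mtl_cox", method_b = m,
          p_value = w$p_value, n_pairs = w$n_pairs,
          better_method = switch(w$direction, a = "mtl_cox", b = m,
                                 none = "none"))
      }
    }
    comparisons <- do.call(rbind, comp_rows)
  }

  final_fit <- if ("mtl_cox" %in% methods) {
    cv_mtl_cox(dataset, n_lambda = n_lambda, min_ratio = min_ratio,
               first_scale = first_scale, nfolds = inner_nfolds,
               control = control)$fit
  } else NULL

  config <- list(methods = methods, nfolds = nfolds,
                 inner_nfolds = inner_nfolds, n_lambda = n_lambda,
                 min_ratio = min_ratio, first_scale = first_scale,
                 horizon_eval = horizon_eval, seed = seed)
  out <- structure(
    list(metrics = metrics, comparisons = comparisons, folds = folds,
         final_fit = final_fit, config = config),
    class = "mtl_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(metrics, file.path(out_dir, "metrics.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    if (!is.null(comparisons)) {
      utils::write.table(comparisons, file.path(out_dir, "comparisons.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(final_fit)) {
      save_mtl_fit(final_fit, file.path(out_dir, "mtl_fit"),
                   standardization = dataset$standardization)
    }
    cfg <- unlist(config)
    utils::write.table(
      data.frame(key = names(cfg), value = unname(cfg)),
      file.path(out_dir, "run_metadata.csv"), sep = ",",
      row.names = FALSE, quote = FALSE)
  }
  out
}

#' @export
print.mtl_experiment <- function(x, ...) {
  cat(sprintf("<mtl_experiment: %d method(s), %d folds>\n",
              length(unique(x$metrics$method)), x$config$nfolds))
  agg <- stats::aggregate(value ~ method + metric, data = x$metrics,
                          FUN = mean, na.rm = TRUE)
  print(stats::reshape(agg, idvar = "method", timevar = "metric",
                       direction = "wide"), row.names = FALSE)
  invisible(x)
}
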