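#' Build an evaluation context for the Cox partial likelihood
#'
#' Pre-sorts one task by decreasing follow-up time so that risk-set sums
#' become reverse cumulative sums, and records tie blocks (subjects sharing
#' a time).  All likelihood, gradient and Hessian evaluations for a task
#' reuse one context.  Ties are handled by the Breslow approximation: every
#' event in a tie block uses the full risk-set denominator.
#'
#' @param task a \code{survival_task} with at least one event.
#' @return An object of class \code{"cox_context"}.
#' @export
cox_context <- function(task) {
  stopifnot(inherits(task, "survival_task"))
  if (sum(task$event) == 0) {
    stop(sprintf("task '%s' has zero events; the partial likelihood is undefined",
                 task$name))
  }
  ord <- order(task$time, decreasing = TRUE)
  time <- task$time[ord]
  # last row of the tie block of each row (descending order, ties adjacent):
  # cumulative sums up to block_last[i] cover every subject with time >= time[i]
  n <- length(time)
  block_last <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && time[j + 1L] == time[i]) j <- j + 1L
    block_last[i:j] <- j
    i <- j + 1L
  }
  structure(
    list(task = task, ord = ord, X = task$X[ord, , drop = FALSE],
         time = time, delta = task$event[ord], block_last = block_last,
         ev = which(task$event[ord] == 1), n = n, p = task$p),
    class = "cox_context"
  )
}

# risk-set denominators and weighted feature sums at each event row,
# shared by nll/gradient; log-sum-exp stabilized
.cox_riskset_sums <- function(beta, ctx, want_num = TRUE) {
  eta <- drop(ctx$X %*% beta)
  m <- max(eta)
  w <- exp(eta - m)
  cw <- cumsum(w)
  bl <- ctx$block_last[ctx$ev]
  out <- list(eta = eta, m = m, w = w,
              log_den = log(cw[bl]) + m,   # log sum_{s in R(T_i)} exp(eta_s)
              den = cw[bl])
  if (want_num) {
    W <- ctx$X * w
    cW <- apply(W, 2, cumsum)
    if (is.null(dim(cW))) cW <- matrix(cW, nrow = 1)
    out$num <- cW[bl, , drop = FALSE]   # sum_{s in R} w_s x_s (unscaled by e^m)
  }
  out
}

#' Negative log partial likelihood of a Cox model
#'
#' Evaluates \deqn{-\sum_{i:\delta_i=1}\Big[x_i\beta -
#'   \log\sum_{s\in R(T_i)} e^{x_s\beta}\Big]} with Breslow handling of
#' tied event times and log-sum-exp stabilization.
#'
#' @param beta coefficient vector of length \code{p}.
#' @param ctx a \code{\link{cox_context}}.
#' @return The scalar negative log partial likelihood.
#' @export
cox_nll <- function(beta, ctx) {
  s <- .cox_riskset_sums(beta, ctx, want_num = FALSE)
  val <- -sum(s$eta[ctx$ev] - s$log_den)
  if (!is.finite(val)) stop("non-finite partial likelihood; check inputs")
  val
}

#' Gradient of the negative log partial likelihood
#'
#' Each event contributes its covariate row minus the exp-weighted mean of
#' its risk set: \deqn{-\sum_{i:\delta_i=1}\Big(x_i - \frac{\sum_{s\in R}
#'   x_s e^{x_s\beta}}{\sum_{s\in R} e^{x_s\beta}}\Big).}
#'
#' @inheritParams cox_nll
#' @return Numeric vector of length \code{p}.
#' @export
cox_gradient <- function(beta, ctx) {
  s <- .cox_riskset_sums(beta, ctx)
  mu <- s$num / s$den   # risk-set weighted means, one row per event
  g <- -(colSums(ctx$X[ctx$ev, , drop = FALSE]) - colSums(mu))
  if (any(!is.finite(g))) stop("non-finite gradient; check inputs")
  g
}

# one pass returning both value and gradient (solver hot path)
cox_nll_grad <- function(beta, ctx) {
  s <- .cox_riskset_sums(beta, ctx)
  val <- -sum(s$eta[ctx$ev] - s$log_den)
  mu <- s$num / s$den
  g <- -(colSums(ctx$X[ctx$ev, , drop = FALSE]) - colSums(mu))
  if (!is.finite(val) || any(!is.finite(g))) {
    stop("non-finite likelihood evaluation; check inputs")
  }
  list(value = val, gradient = g)
}

#' Hessian of the negative log partial likelihood
#'
#' Sum over events of the exp-weighted risk-set covariance of the
#' covariates; symmetric positive semidefinite.
#'
#' @inheritParams cox_nll
#' @return A \code{p x p} symmetric matrix.
#' @export
cox_hessian <- function(beta, ctx) {
  eta <- drop(ctx$X %*% beta)
  m <- max(eta)
  w <- exp(eta - m)
  p <- ctx$p
  H <- matrix(0, p, p)
  # walk tie blocks in descending time, accumulating D, S1, S2 incrementally
  bl_ev <- ctx$block_last[ctx$ev]
  d_at <- table(bl_ev)                       # events per block (Breslow d_i)
  need <- as.integer(names(d_at))            # block-last rows with events
  D <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  prev <- 0L
  for (k in seq_along(need)) {
    rows <- (prev + 1L):need[k]
    Xc <- ctx$X[rows, , drop = FALSE]
    wc <- w[rows]
    D <- D + sum(wc)
    S1 <- S1 + colSums(Xc * wc)
    S2 <- S2 + crossprod(Xc, Xc * wc)
    mu <- S1 / D
    H <- H + as.numeric(d_at[k]) * (S2 / D - tcrossprod(mu))
    prev <- need[k]
  }
  (H + t(H)) / 2
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' \deqn{H_0(t) = \sum_{T_i \le t} d_i / \sum_{s\in R(T_i)} e^{x_s\beta}}
#' where \eqn{d_i} counts events at \eqn{T_i}.  With \eqn{\beta = 0} and no
#' ties this is the Nelson--Aalen estimator.
#'
#' @param beta fitted coefficient vector.
#' @param ctx a \code{\link{cox_context}}.
#' @return An object of class \code{"baseline_hazard"}: list with
#'   \code{task_name}, \code{event_times} (ascending), \code{cumhaz}
#'   (nondecreasing step values), and \code{max_time} (largest observed
#'   follow-up).
#' @export
breslow_baseline <- function(beta, ctx) {
  s <- .cox_riskset_sums(beta, ctx, want_num = FALSE)
  bl <- ctx$block_last[ctx$ev]
  d_at <- table(bl)
  need <- as.integer(names(d_at))
  tt <- ctx$time[need]                  # descending distinct event times
  inc <- as.numeric(d_at) / exp(log(cumsum(s$w)[need]) + s$m)
  o <- order(tt)
  structure(
    list(task_name = ctx$task$name, event_times = tt[o],
         cumhaz = cumsum(inc[o]), max_time = max(ctx$task$time)),
    class = "baseline_hazard"
  )
}

#' Evaluate a cumulative baseline hazard at given times
#'
#' @param baseline a \code{\link{breslow_baseline}} result.
#' @param times numeric vector of times.
#' @param warn warn when a time exceeds the last observed follow-up (the
#'   hazard is held at its last step).
#' @return \eqn{H_0(t)} at each time (0 before the first event time).
#' @export
baseline_cumhaz <- function(baseline, times, warn = TRUE) {
  if (warn && any(times > baseline$max_time)) {
    warning(sprintf("horizon beyond last observed time (%.3g); using last hazard step",
                    baseline$max_time))
  }
  idx <- findInterval(times, baseline$event_times)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat(sprintf("<baseline_hazard '%s': %d event times, H0(max)=%.4f>\n",
              x$task_name, length(x$event_times),
              x$cumhaz[length(x$cumhaz)]))
  invisible(x)
}

#' Write a baseline hazard as two-column delimited text
#'
#' @param baseline a \code{baseline_hazard}.
#' @param path output file; columns \code{time}, \code{cumulative_hazard}.
#' @export
write_baseline <- function(baseline, path) {
  utils::write.table(
    data.frame(time = baseline$event_times,
               cumulative_hazard = baseline$cumhaz),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Absolute risk of an event by a fixed horizon
#'
#' Under proportional hazards the probability of the event by horizon
#' \eqn{h} for a subject with covariates \eqn{x} is
#' \deqn{AR = 1 - \exp\{-H_0(h)\, e^{x\beta}\}.}
#'
#' @param x feature vector (or matrix, one subject per row) on the same
#'   scale as the training design.
#' @param beta fitted coefficient vector.
#' @param baseline a \code{\link{breslow_baseline}} result.
#' @param horizon positive horizon in years.
#' @return Absolute risk(s) in \eqn{[0,1]}.
#' @export
absolute_risk <- function(x, beta, baseline, horizon) {
  stopifnot(horizon > 0)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  H0 <- baseline_cumhaz(baseline, horizon)
  drop(1 - exp(-H0 * exp(x %*% beta)))
}
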