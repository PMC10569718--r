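# small random right-censored task; seeds are set by the calling test
random_task <- function(n = 30, p = 4, name = "t", censor = 0.3,
                        tie_prob = 0) {
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  time <- rexp(n) + 0.05
  if (tie_prob > 0) time <- round(time, 1) + 0.05   # force tied times
  event <- rbinom(n, 1, 1 - censor)
  if (sum(event) == 0) event[sample(n, 2)] <- 1
  survival_task(name, X, time, event)
}

# the 2-subject toy: times (1, 2), both events, single feature x = (1, 0)
toy2 <- function() {
  survival_task("toy", matrix(c(1, 0), 2, 1, dimnames = list(NULL, "x")),
                c(1, 2), c(1, 1))
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# exhaustive comparable-pair enumeration (independent C-index oracle)
c_index_bruteforce <- function(scores, time, event) {
  conc <- 0; total <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        total <- total + 1
        if (scores[i] > scores[j]) conc <- conc + 1
        else if (scores[i] == scores[j]) conc <- conc + 0.5
      }
    }
  }
  if (total == 0) NA_real_ else conc / total
}

# trapezoidal ROC integration over all thresholds (independent AUC oracle)
auc_trapezoid <- function(risk, labels) {
  keep <- !is.na(labels)
  risk <- risk[keep]; labels <- labels[keep]
  th <- c(Inf, sort(unique(risk), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(risk[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(risk[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# numerical minimizer of the row-separable prox objective (oracle for
# prox_l21): the solution lies on the ray along g, so minimize the convex
# 1-D objective 0.5 (||g|| - a)^2 + tau * a over a in [0, ||g||]
prox_row_oracle <- function(g, tau) {
  ng <- sqrt(sum(g^2))
  if (ng == 0) return(g)
  f <- function(a) 0.5 * (ng - a)^2 + tau * a
  a <- stats::optimize(f, c(0, ng), tol = 1e-10)$minimum
  # the objective is quadratic in a: one parabolic-vertex step is exact
  h <- 1e-3
  denom <- f(a + h) - 2 * f(a) + f(a - h)
  if (denom > 0) a <- a - h / 2 * (f(a + h) - f(a - h)) / denom
  a <- min(max(a, 0), ng)
  if (f(0) <= f(a)) a <- 0                  # boundary solution
  g / ng * a
}
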