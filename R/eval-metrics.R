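#' Harrell concordance index for censored predictions
#'
#' A pair (i, j) is comparable when subject i has an observed event and
#' strictly shorter follow-up than subject j.  The C-index is the fraction
#' of comparable pairs in which the shorter-lived subject has the higher
#' risk score; tied scores count one half.
#'
#' @param scores risk scores (higher = higher risk), e.g. the Cox linear
#'   predictor \eqn{x\hat\beta}.
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @param na_if_undefined return \code{NA} instead of erroring when no
#'   comparable pair exists.
#' @return Scalar in \eqn{[0,1]}, with attribute \code{n_pairs}.
#' @export
c_index <- function(scores, time, event, na_if_undefined = FALSE) {
  ev <- which(event == 1)
  if (length(ev) == 0) {
    if (na_if_undefined) return(NA_real_)
    stop("no events: C-index undefined")
  }
  cmp <- outer(time[ev], time, "<")          # comparable: i event, t_i < t_j
  n_pairs <- sum(cmp)
  if (n_pairs == 0) {
    if (na_if_undefined) return(NA_real_)
    stop("no comparable pairs: C-index undefined")
  }
  conc <- outer(scores[ev], scores, ">") + 0.5 * outer(scores[ev], scores, "==")
  structure(sum(conc * cmp) / n_pairs, n_pairs = n_pairs)
}

#' Convert censored follow-up to binary labels at a horizon
#'
#' Positive: event observed at or before the horizon.  Negative: follow-up
#' (event or censoring) extends beyond the horizon.  Subjects censored at
#' or before the horizon without an event carry no label and are excluded
#' (masked) rather than treated as negatives.
#'
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @param horizon classification horizon (years).
#' @return List with \code{labels} (0/1/\code{NA}) and logical
#'   \code{included}.
#' @export
binarize_at_horizon <- function(time, event, horizon) {
  labels <- rep(NA_real_, length(time))
  labels[event == 1 & time <= horizon] <- 1
  labels[time > horizon] <- 0
  list(labels = labels, included = !is.na(labels))
}

#' ROC area under the curve with Youden-optimal cutoff
#'
#' AUC by the rank (Mann--Whitney) formulation; the cutoff is the risk
#' threshold maximizing Youden's index (sensitivity + specificity - 1)
#' along the ROC curve, with the highest threshold kept on ties.
#' \code{NA} labels are dropped.
#'
#' @param risk predicted risks (higher = more likely positive).
#' @param labels 0/1 labels (\code{NA} allowed, excluded).
#' @return List with \code{auc}, \code{cutoff}, \code{sensitivity},
#'   \code{specificity}, \code{youden} at the chosen cutoff; all \code{NA}
#'   with \code{defined = FALSE} when only one class is present.
#' @export
roc_auc <- function(risk, labels) {
  keep <- !is.na(labels) & !is.na(risk)
  risk <- risk[keep]; labels <- labels[keep]
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    return(list(auc = NA_real_, cutoff = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, youden = NA_real_, defined = FALSE))
  }
  r <- rank(risk)                            # midranks handle score ties
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(risk, decreasing = TRUE)
  rs <- risk[ord]; ls <- labels[ord]
  # last index of each block of tied risk values
  last <- c(which(rs[-length(rs)] != rs[-1]), length(rs))
  sens <- cumsum(ls)[last] / npos            # predict positive if risk >= cutoff
  fpr <- cumsum(1 - ls)[last] / nneg
  youden <- sens - fpr
  best <- which.max(youden)
  list(auc = auc, cutoff = rs[last[best]], sensitivity = sens[best],
       specificity = 1 - fpr[best], youden = youden[best], defined = TRUE)
}

#' Sensitivity, specificity and Youden index at a fixed cutoff
#'
#' Predicted positive when \code{risk >= cutoff}; sensitivity
#' = TP/(TP+FN), specificity = TN/(TN+FP), Youden = sensitivity +
#' specificity - 1 (identity exact).
#'
#' @inheritParams roc_auc
#' @param cutoff decision threshold on the risk scale.
#' @return List with \code{sensitivity}, \code{specificity},
#'   \code{youden}.
#' @export
confusion_metrics <- function(risk, labels, cutoff) {
  keep <- !is.na(labels) & !is.na(risk)
  risk <- risk[keep]; labels <- labels[keep]
  pred <- as.numeric(risk >= cutoff)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec, youden = sens + spec - 1)
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on paired metric differences (typically one
#' pair per disease x fold).  Zero differences are dropped; the exact null
#' distribution is used for at most 25 informative pairs without tied
#' absolute differences, otherwise the normal approximation with
#' continuity correction.
#'
#' @param a,b paired metric values (same length, same ordering of pairs).
#' @return List with \code{p_value}, \code{statistic} (V), \code{n_pairs}
#'   (informative pairs), \code{direction} (\code{"a"}, \code{"b"} or
#'   \code{"none"}, whichever tends larger), and \code{all_equal}.
#' @export
paired_wilcoxon <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p_value = 1, statistic = NA_real_, n_pairs = 0,
                direction = "none", all_equal = TRUE))
  }
  use_exact <- n <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = TRUE))
  v <- unname(wt$statistic)
  list(p_value = wt$p.value, statistic = v, n_pairs = n,
       direction = if (v > n * (n + 1) / 4) "a"
                   else if (v < n * (n + 1) / 4) "b" else "none",
       all_equal = FALSE)
}
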