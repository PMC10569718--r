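#' Absolute-risk table for a set of subjects across diseases and horizons
#'
#' Scores one shared feature matrix under every task model of a fitted
#' multitask Cox model: for each disease and horizon, the probability of
#' the event by the horizon given the subject's covariates.  Diseases are
#' separate models, so a subject's risks do not sum to anything in
#' particular.
#'
#' @param fit an \code{mtl_cox_fit} with baselines.
#' @param newX feature matrix (subjects x features) on the same scale as
#'   the training design (apply the stored standardization first).
#' @param horizons numeric vector of horizons in years (default 1, 3, 5, 7).
#' @param ids optional subject identifiers.
#' @return Data frame with columns \code{id}, \code{disease},
#'   \code{horizon}, \code{ar}.
#' @export
risk_table <- function(fit, newX, horizons = c(1, 3, 5, 7), ids = NULL) {
  stopifnot(inherits(fit, "mtl_cox_fit"), !is.null(fit$baselines))
  newX <- as.matrix(newX)
  if (is.null(ids)) ids <- seq_len(nrow(newX))
  out <- expand.grid(id = ids, disease = fit$task_names, horizon = horizons,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ar <- numeric(nrow(out))
  i <- 1L
  for (h in horizons) {
    for (k in seq_along(fit$task_names)) {
      ar[seq.int(i, length.out = nrow(newX))] <-
        absolute_risk(newX, fit$B[, k], fit$baselines[[k]], h)
      i <- i + nrow(newX)
    }
  }
  out$ar <- ar
  out
}

.age_group <- function(age, breaks = c(40, 50, 60, 70),
                       labels = c("40-49", "50-59", "60-69", "70+")) {
  cut(age, breaks = c(breaks, Inf), labels = labels, right = FALSE)
}

#' Basis risk: age-group mean absolute risk
#'
#' The population reference level against which individual risks are
#' judged: the mean absolute risk within each age group, per disease and
#' horizon (age groups 40-49, 50-59, 60-69, 70+ by default).
#'
#' @param risk_tab a \code{\link{risk_table}} result.
#' @param age named or ordered numeric vector of ages, one per subject id
#'   appearing in \code{risk_tab}.
#' @param age_breaks lower bounds of the age groups.
#' @param age_labels group labels.
#' @return Data frame with \code{disease}, \code{age_group},
#'   \code{horizon}, \code{basis_ar}, \code{n}; empty groups are absent.
#' @export
basis_risk <- function(risk_tab, age, age_breaks = c(40, 50, 60, 70),
                       age_labels = c("40-49", "50-59", "60-69", "70+")) {
  ids <- unique(risk_tab$id)
  stopifnot(length(age) == length(ids))
  grp <- .age_group(age, age_breaks, age_labels)
  risk_tab$age_group <- grp[match(risk_tab$id, ids)]
  agg <- stats::aggregate(ar ~ disease + age_group + horizon,
                          data = risk_tab, FUN = mean, drop = TRUE)
  cnt <- stats::aggregate(ar ~ disease + age_group + horizon,
                          data = risk_tab, FUN = length, drop = TRUE)
  names(agg)[names(agg) == "ar"] <- "basis_ar"
  agg$n <- cnt$ar
  agg
}

#' Relative and excess absolute risk per subject
#'
#' For every subject x disease x horizon record: relative absolute risk
#' RAR = AR / basis risk of the subject's age group (a multiple of the
#' group average), and excess absolute risk EAR = AR - basis risk (also
#' given in percentage points as \code{ear_pct}).  RAR is undefined
#' (\code{NA}) when the basis risk is zero.
#'
#' @param risk_tab a \code{\link{risk_table}} result.
#' @param basis a \code{\link{basis_risk}} result.
#' @param age ages aligned with the unique subject ids of \code{risk_tab}.
#' @param age_breaks,age_labels age grouping, matching \code{basis}.
#' @return Data frame: \code{id}, \code{disease}, \code{horizon},
#'   \code{age_group}, \code{ar}, \code{basis_ar}, \code{rar}, \code{ear},
#'   \code{ear_pct}.
#' @export
relative_and_excess <- function(risk_tab, basis, age,
                                age_breaks = c(40, 50, 60, 70),
                                age_labels = c("40-49", "50-59", "60-69", "70+")) {
  ids <- unique(risk_tab$id)
  stopifnot(length(age) == length(ids))
  risk_tab$age_group <- .age_group(age, age_breaks, age_labels)[match(risk_tab$id, ids)]
  out <- merge(risk_tab, basis[, c("disease", "age_group", "horizon", "basis_ar")],
               by = c("disease", "age_group", "horizon"), all.x = TRUE,
               sort = FALSE)
  out$rar <- ifelse(out$basis_ar > 0, out$ar / out$basis_ar, NA_real_)
  out$ear <- out$ar - out$basis_ar
  out$ear_pct <- 100 * out$ear
  out[order(out$id, out$disease, out$horizon),
      c("id", "disease", "horizon", "age_group", "ar", "basis_ar",
        "rar", "ear", "ear_pct")]
}

#' Quantile risk-stratum boundaries
#'
#' Sorts absolute risks into their 33%, 50% and 66% quantiles (linear
#' interpolation between order statistics) to obtain the upper bound of
#' the low-risk group, the median of the average-risk group, and the lower
#' bound of the high-risk group — per disease and horizon, and by default
#' within each age group.
#'
#' @param risk_tab a \code{\link{risk_table}} result.
#' @param age optional ages (required when \code{by_age = TRUE}).
#' @param quantiles the three probability levels.
#' @param by_age compute boundaries within age groups (default) or pooled
#'   over ages.
#' @param age_breaks,age_labels age grouping.
#' @return Data frame of class \code{"risk_strata"} with columns
#'   \code{disease}, (\code{age_group}), \code{horizon},
#'   \code{low_upper}, \code{average_mid}, \code{high_lower}.
#' @export
risk_strata <- function(risk_tab, age = NULL,
                        quantiles = c(0.33, 0.50, 0.66), by_age = !is.null(age),
                        age_breaks = c(40, 50, 60, 70),
                        age_labels = c("40-49", "50-59", "60-69", "70+")) {
  stopifnot(length(quantiles) == 3, !is.unsorted(quantiles))
  if (by_age) {
    stopifnot(!is.null(age))
    ids <- unique(risk_tab$id)
    risk_tab$age_group <- .age_group(age, age_breaks, age_labels)[match(risk_tab$id, ids)]
    by_cols <- c("disease", "age_group", "horizon")
  } else {
    by_cols <- c("disease", "horizon")
  }
  qf <- function(x) stats::quantile(x, quantiles, names = FALSE, type = 7)
  agg <- stats::aggregate(risk_tab["ar"], risk_tab[by_cols],
                          FUN = function(x) qf(x))
  q <- as.data.frame(agg$ar)
  names(q) <- c("low_upper", "average_mid", "high_lower")
  out <- cbind(agg[by_cols], q)
  class(out) <- c("risk_strata", "data.frame")
  out
}

#' Assign risk strata to subjects
#'
#' Labels each record low / average / high against the quantile
#' boundaries: \code{ar <= low_upper} is low, \code{ar >= high_lower} is
#' high, anything between is average.  A risk exactly at the 33% quantile
#' is low (boundary inclusive downward); when all boundaries coincide
#' every record is average.
#'
#' @param risk_tab a \code{\link{risk_table}} result (with
#'   \code{age_group} column when the strata are age-specific; supply
#'   \code{age} to add it).
#' @param strata a \code{\link{risk_strata}} result.
#' @param age optional ages used to attach age groups.
#' @param age_breaks,age_labels age grouping.
#' @return \code{risk_tab} with an added factor column \code{stratum}.
#' @export
stratify <- function(risk_tab, strata, age = NULL,
                     age_breaks = c(40, 50, 60, 70),
                     age_labels = c("40-49", "50-59", "60-69", "70+")) {
  by_cols <- intersect(c("disease", "age_group", "horizon"), names(strata))
  if ("age_group" %in% by_cols && !"age_group" %in% names(risk_tab)) {
    stopifnot(!is.null(age))
    ids <- unique(risk_tab$id)
    risk_tab$age_group <- .age_group(age, age_breaks, age_labels)[match(risk_tab$id, ids)]
  }
  m <- merge(risk_tab, as.data.frame(strata), by = by_cols, all.x = TRUE,
             sort = FALSE)
  degenerate <- m$low_upper == m$high_lower
  m$stratum <- ifelse(degenerate, "average",
               ifelse(m$ar <= m$low_upper, "low",
               ifelse(m$ar >= m$high_lower, "high", "average")))
  m$stratum <- factor(m$stratum, levels = c("low", "average", "high"))
  m[, c(names(risk_tab), "stratum")]
}

#' Rank diseases by absolute risk for each subject
#'
#' Orders the diseases by decreasing absolute risk at one horizon; rank 1
#' is the highest risk.  Ties are broken by disease-name order so the
#' ranking is invariant to the column ordering of the input.
#'
#' @param risk_tab a \code{\link{risk_table}} result.
#' @param horizon the horizon (years) to rank at.
#' @return Data frame \code{id}, \code{disease}, \code{ar}, \code{rank},
#'   ordered by subject then rank.
#' @export
rank_diseases <- function(risk_tab, horizon) {
  sub <- risk_tab[risk_tab$horizon == horizon, ]
  if (nrow(sub) == 0) stop("no records at the requested horizon")
  sub <- sub[order(sub$id, -sub$ar, sub$disease), ]
  sub$rank <- stats::ave(sub$ar, sub$id, FUN = seq_along)
  rownames(sub) <- NULL
  sub[, c("id", "disease", "ar", "rank")]
}

#' Write the personalized risk reports as delimited text
#'
#' Emits the per-subject absolute/relative/excess risk table and the
#' stratum boundary table into a directory.
#'
#' @param profiles a \code{\link{relative_and_excess}} result.
#' @param strata a \code{\link{risk_strata}} result.
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_risk_reports <- function(profiles, strata, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(profiles, file.path(dir, "risk_profiles.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(strata),
                     file.path(dir, "risk_strata.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
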