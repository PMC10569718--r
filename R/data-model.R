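#' Construct a single-task right-censored survival dataset
#'
#' A \code{survival_task} bundles the design matrix, follow-up times and
#' event indicators for one disease (one "task").  Times are measured in
#' years from enrollment; \code{event = 1} marks an observed diagnosis,
#' \code{event = 0} a right-censored subject.
#'
#' @param name task label (e.g. the disease name).
#' @param X numeric feature matrix, one row per subject.  Column names are
#'   required; they define the feature identity used to align tasks.
#' @param time positive numeric vector of follow-up times (years).
#' @param event integer/numeric vector of 0/1 event indicators.
#' @param id optional subject identifiers; defaults to row numbers.
#'
#' @return An object of class \code{"survival_task"}: a list with elements
#'   \code{name}, \code{X}, \code{time}, \code{event}, \code{id}, \code{n}
#'   and \code{p}.
#' @export
survival_task <- function(name, X, time, event, id = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    stop("feature matrix must have column names")
  }
  n <- nrow(X)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != n || length(event) != n) {
    stop("time and event must have one entry per row of X")
  }
  if (anyNA(X) || anyNA(time) || anyNA(event)) {
    stop("missing values are not allowed in a validated task")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all times must be strictly positive and finite")
  }
  if (!all(event %in% c(0, 1))) {
    stop(sprintf("task '%s': event indicator must be 0 or 1", name))
  }
  if (is.null(id)) id <- seq_len(n)
  structure(
    list(name = as.character(name), X = X, time = time, event = event,
         id = id, n = n, p = ncol(X)),
    class = "survival_task"
  )
}

#' @export
print.survival_task <- function(x, ...) {
  cat(sprintf("<survival_task '%s': %d subjects, %d features, %d events (%.1f%% censored)>\n",
              x$name, x$n, x$p, sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' Construct a multitask survival dataset
#'
#' Bundles K \code{survival_task} objects that share one feature registry
#' (identical feature names, identical column order, and a declared kind —
#' continuous or binary — per feature).
#'
#' @param tasks list of \code{survival_task} objects.
#' @param registry data frame with columns \code{name} and \code{kind}
#'   (\code{"continuous"} or \code{"binary"}).  If omitted, every feature is
#'   assumed continuous.
#'
#' @return An object of class \code{"multitask_dataset"}: a list with
#'   elements \code{tasks} (named list), \code{registry}, \code{K},
#'   \code{p}, and \code{standardization} (\code{NULL} until
#'   \code{\link{standardize}} is applied).
#' @export
multitask_dataset <- function(tasks, registry = NULL) {
  if (length(tasks) < 1) stop("need at least one task")
  stopifnot(all(vapply(tasks, inherits, logical(1), "survival_task")))
  nms <- vapply(tasks, function(t) t$name, character(1))
  if (anyDuplicated(nms)) stop("task names must be unique")
  feat <- colnames(tasks[[1]]$X)
  for (t in tasks) {
    if (!identical(colnames(t$X), feat)) {
      stop(sprintf("task '%s' does not match the shared feature registry", t$name))
    }
  }
  if (is.null(registry)) {
    registry <- data.frame(name = feat, kind = "continuous",
                           stringsAsFactors = FALSE)
  }
  if (!identical(registry$name, feat)) {
    stop("registry feature names must match task columns in order")
  }
  if (!all(registry$kind %in% c("continuous", "binary"))) {
    stop("feature kind must be 'continuous' or 'binary'")
  }
  names(tasks) <- nms
  structure(
    list(tasks = tasks, registry = registry, K = length(tasks),
         p = length(feat), standardization = NULL),
    class = "multitask_dataset"
  )
}

#' @export
print.multitask_dataset <- function(x, ...) {
  cat(sprintf("<multitask_dataset: K=%d tasks, P=%d shared features%s>\n",
              x$K, x$p,
              if (is.null(x$standardization)) "" else ", standardized"))
  for (t in x$tasks) print(t)
  invisible(x)
}

#' Load per-task survival tables from delimited text files
#'
#' Each file holds one task: columns \code{id}, \code{time}, \code{event}
#' followed by the shared feature columns.  Rows with missing required
#' values are dropped with a per-row report.
#'
#' @param paths named character vector of file paths; names become task
#'   names (basename without extension when unnamed).
#' @param registry feature registry (see \code{\link{multitask_dataset}});
#'   if \code{NULL} it is inferred from the first file's non-reserved
#'   columns, all marked continuous.
#' @param columns named list mapping the reserved roles to column names;
#'   default \code{list(id = "id", time = "time", event = "event")}.
#' @param sep field separator, comma by default.
#' @param time_unit \code{"years"} (default) or \code{"days"}; day-scale
#'   input is converted at 365.25 days per year.
#'
#' @return A \code{multitask_dataset}.  Dropped rows are reported via
#'   \code{message()} and recorded in \code{attr(, "dropped_rows")}.
#' @export
load_tasks <- function(paths, registry = NULL,
                       columns = list(id = "id", time = "time", event = "event"),
                       sep = ",", time_unit = c("years", "days")) {
  time_unit <- match.arg(time_unit)
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  dropped <- list()
  tasks <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    f <- paths[[i]]
    df <- utils::read.table(f, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    for (role in c("id", "time", "event")) {
      col <- columns[[role]]
      if (!col %in% names(df)) {
        stop(sprintf("file '%s' lacks required column '%s'", f, col))
      }
    }
    if (is.null(registry)) {
      feat <- setdiff(names(df), unlist(columns))
      registry <- data.frame(name = feat, kind = "continuous",
                             stringsAsFactors = FALSE)
    }
    miss <- setdiff(registry$name, names(df))
    if (length(miss) > 0) {
      stop(sprintf("file '%s' lacks feature column(s): %s",
                   f, paste(miss, collapse = ", ")))
    }
    need <- c(unlist(columns), registry$name)
    ok <- stats::complete.cases(df[, need])
    if (any(!ok)) {
      dropped[[names(paths)[i]]] <- which(!ok)
      message(sprintf("task '%s': dropped %d row(s) with missing values (rows %s)",
                      names(paths)[i], sum(!ok),
                      paste(utils::head(which(!ok), 10), collapse = ", ")))
      df <- df[ok, , drop = FALSE]
    }
    ev <- df[[columns$event]]
    if (!all(ev %in% c(0, 1))) {
      bad <- unique(ev[!ev %in% c(0, 1)])
      stop(sprintf("file '%s': event column '%s' contains non-binary value(s): %s",
                   f, columns$event, paste(bad, collapse = ", ")))
    }
    tt <- df[[columns$time]]
    if (time_unit == "days") tt <- tt / 365.25
    tasks[[i]] <- survival_task(
      name = names(paths)[i],
      X = as.matrix(df[, registry$name, drop = FALSE]),
      time = tt, event = ev, id = df[[columns$id]]
    )
  }
  out <- multitask_dataset(tasks, registry)
  attr(out, "dropped_rows") <- dropped
  out
}

#' Write a multitask dataset back to per-task delimited files
#'
#' Inverse of \code{\link{load_tasks}}: one file per task with columns
#' \code{id}, \code{time}, \code{event} and the features.
#'
#' @param dataset a \code{multitask_dataset}.
#' @param dir output directory (created if absent).
#' @param sep field separator.
#' @return Invisibly, the vector of file paths written.
#' @export
write_tasks <- function(dataset, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(dataset$K)
  for (i in seq_len(dataset$K)) {
    t <- dataset$tasks[[i]]
    df <- data.frame(id = t$id, time = t$time, event = t$event,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(t$X, check.names = FALSE))
    paths[i] <- file.path(dir, paste0(t$name, ".csv"))
    utils::write.table(df, paths[i], sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(stats::setNames(paths, names(dataset$tasks)))
}

#' Standardize continuous features of a multitask dataset
#'
#' Centers and scales each continuous feature to mean 0 and sample standard
#' deviation 1 (n-1 denominator), either pooling subjects across all tasks
#' or within each task.  Binary features are untouched.  The fitted
#' center/scale are stored so the identical transform can be applied to new
#' subjects with \code{\link{apply_standardization}}.
#'
#' @param dataset a \code{multitask_dataset}.
#' @param scope \code{"pooled"} (default) or \code{"per_task"}.
#' @return The standardized \code{multitask_dataset}, with the transform
#'   recorded in \code{$standardization}.
#' @export
standardize <- function(dataset, scope = c("pooled", "per_task")) {
  scope <- match.arg(scope)
  cont <- dataset$registry$kind == "continuous"
  if (scope == "pooled") {
    pooled <- do.call(rbind, lapply(dataset$tasks, function(t) t$X))
    ctr <- colMeans(pooled)
    scl <- apply(pooled, 2, stats::sd)
    ctr[!cont] <- 0
    scl[!cont] <- 1
    zv <- cont & (scl == 0 | !is.finite(scl))
    if (any(zv)) {
      warning(sprintf("zero-variance continuous feature(s) left centered only: %s",
                      paste(dataset$registry$name[zv], collapse = ", ")))
      scl[zv] <- 1
    }
    for (i in seq_len(dataset$K)) {
      dataset$tasks[[i]]$X <- sweep(sweep(dataset$tasks[[i]]$X, 2, ctr), 2, scl, "/")
    }
    dataset$standardization <- list(scope = scope, center = ctr, scale = scl)
  } else {
    per <- vector("list", dataset$K)
    for (i in seq_len(dataset$K)) {
      X <- dataset$tasks[[i]]$X
      ctr <- colMeans(X)
      scl <- apply(X, 2, stats::sd)
      ctr[!cont] <- 0
      scl[!cont] <- 1
      zv <- cont & (scl == 0 | !is.finite(scl))
      if (any(zv)) {
        warning(sprintf("task '%s': zero-variance continuous feature(s) left centered only: %s",
                        dataset$tasks[[i]]$name,
                        paste(dataset$registry$name[zv], collapse = ", ")))
        scl[zv] <- 1
      }
      dataset$tasks[[i]]$X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      per[[i]] <- list(center = ctr, scale = scl)
    }
    names(per) <- names(dataset$tasks)
    dataset$standardization <- list(scope = scope, per_task = per)
  }
  dataset
}

#' Apply a stored standardization transform to new feature rows
#'
#' @param newX numeric matrix of raw feature values, columns matching the
#'   registry.
#' @param standardization the \code{$standardization} element of a
#'   standardized \code{multitask_dataset}.
#' @param task task name, required when the transform was fitted per task.
#' @return The transformed matrix.
#' @export
apply_standardization <- function(newX, standardization, task = NULL) {
  if (is.null(standardization)) return(newX)
  if (standardization$scope == "pooled") {
    ctr <- standardization$center; scl <- standardization$scale
  } else {
    if (is.null(task)) stop("per-task standardization requires a task name")
    ctr <- standardization$per_task[[task]]$center
    scl <- standardization$per_task[[task]]$scale
  }
  sweep(sweep(as.matrix(newX), 2, ctr), 2, scl, "/")
}

#' Build the risk-set index of a survival task
#'
#' For each distinct event time \eqn{T_i} the risk set \eqn{R(T_i)} holds
#' every subject whose follow-up time is at least \eqn{T_i}; tied event
#' times form one tie group sharing a risk set (Breslow convention
#' downstream).
#'
#' @param task a \code{survival_task}.
#' @return An object of class \code{"risk_set_index"}: list with
#'   \code{event_times} (ascending distinct event times), \code{risk_sets}
#'   (list of subject index vectors), \code{event_members} (list of indices
#'   of subjects whose event occurs at each time), and \code{n_events}
#'   (tie-group sizes).
#' @export
build_risk_sets <- function(task) {
  stopifnot(inherits(task, "survival_task"))
  if (sum(task$event) == 0) {
    stop(sprintf("task '%s' has zero events; the partial likelihood is undefined",
                 task$name))
  }
  et <- sort(unique(task$time[task$event == 1]))
  risk_sets <- lapply(et, function(tt) which(task$time >= tt))
  event_members <- lapply(et, function(tt) which(task$time == tt & task$event == 1))
  structure(
    list(event_times = et, risk_sets = risk_sets,
         event_members = event_members,
         n_events = vapply(event_members, length, integer(1))),
    class = "risk_set_index"
  )
}
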