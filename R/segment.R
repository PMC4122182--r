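#' One subject's data for one condition
#'
#' @param matrix numeric matrix, time points x ROIs, with ROI column names.
#' @param condition condition label.
#' @param subject_id subject identifier.
#' @param standardized whether columns are already z-scored.
#' @return An object of class `condition_dataset`.
#' @export
condition_dataset <- function(matrix, condition, subject_id,
                              standardized = FALSE) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix))) stop("matrix must have ROI column names")
  if (anyNA(matrix)) stop("matrix contains missing values")
  structure(list(matrix = matrix,
                 condition = condition,
                 subject_id = subject_id,
                 n = nrow(matrix),
                 standardized = isTRUE(standardized)),
            class = "condition_dataset")
}

#' @export
print.condition_dataset <- function(x, ...) {
  cat(sprintf("Condition dataset: %s / %s, %d time points x %d ROIs%s\n",
              x$subject_id, x$condition, x$n, ncol(x$matrix),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Slice a subject's time series into per-condition datasets
#'
#' Rows of all segments with the same condition label are concatenated in
#' time order into one dataset per condition.  Rest segments are analyzed
#' starting `rest_trim_seconds` after the end of the preceding task block:
#' the first `ceiling(rest_trim_seconds / tr_seconds)` TRs of every rest
#' segment are dropped (2 TRs at TR = 2 s, so 5-6 TR rests contribute
#' their last 3-4 TRs).  TR indices are 0-based and segments half-open.
#'
#' @param ts a [simulate_subject()] result (or `roi_timeseries`).
#' @param schedule a `block_schedule`; must fit within `ts`.
#' @param rest_trim_seconds seconds of each rest segment to discard.
#' @return named list of unstandardized [condition_dataset()] objects, one
#'   per condition present in the schedule; attribute `dropped_rows` counts
#'   the trimmed rest TRs.
#' @export
segment <- function(ts, schedule, rest_trim_seconds = 4) {
  stopifnot(inherits(ts, "roi_timeseries"),
            inherits(schedule, "block_schedule"))
  n_total <- nrow(ts$values)
  if (nrow(schedule) == 0L)
    return(structure(list(), dropped_rows = 0L))
  ends <- schedule$onset_tr + schedule$n_trs
  over <- which(ends > n_total | schedule$onset_tr < 0L)
  if (length(over))
    stop("schedule segment ", over[1L], " (", schedule$condition[over[1L]],
         ") overruns the series (", n_total, " TRs)")
  ord <- order(schedule$onset_tr)
  if (any(ends[ord][-length(ord)] > schedule$onset_tr[ord][-1L]))
    stop("schedule segments overlap")
  tr <- attr(schedule, "tr_seconds")
  trim <- as.integer(ceiling(rest_trim_seconds / tr))
  dropped <- 0L
  rows <- list()
  for (r in ord) {
    cond <- schedule$condition[r]
    idx <- seq.int(schedule$onset_tr[r] + 1L, ends[r])  # 1-based rows
    if (cond == "rest") {
      k <- min(trim, length(idx))
      dropped <- dropped + k
      idx <- idx[seq_along(idx) > k]
    }
    rows[[cond]] <- c(rows[[cond]], idx)
  }
  out <- lapply(names(rows), function(cond)
    condition_dataset(ts$values[rows[[cond]], , drop = FALSE],
                      condition = cond, subject_id = ts$subject_id))
  names(out) <- names(rows)
  structure(out, dropped_rows = dropped)
}

#' Column-wise z-scoring of a condition dataset
#'
#' Centers each ROI column and scales it to unit sample variance
#' (divisor n - 1).  Structure search and orientation operate on
#' standardized data with intercept-free regressions, so standardization
#' is a required step between segmentation and analysis.
#'
#' @param ds a [condition_dataset()].
#' @param on_constant what to do with zero-variance columns: `"error"`
#'   (default) or `"flag"` (column set to all zeros and its name recorded
#'   in the `zero_variance` attribute).
#' @return the standardized `condition_dataset`.
#' @export
standardize <- function(ds, on_constant = c("error", "flag")) {
  stopifnot(inherits(ds, "condition_dataset"))
  on_constant <- match.arg(on_constant)
  if (ds$n < 2L) stop("need at least 2 time points to standardize")
  m <- ds$matrix
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu)
  s <- sqrt(colSums(m^2) / (nrow(m) - 1L))
  zero <- colnames(m)[s == 0]
  if (length(zero)) {
    if (on_constant == "error")
      stop("zero-variance column(s): ", paste(zero, collapse = ", "))
    s[s == 0] <- 1
  }
  m <- sweep(m, 2L, s, "/")
  out <- condition_dataset(m, ds$condition, ds$subject_id,
                           standardized = TRUE)
  attr(out, "zero_variance") <- zero
  out
}

#' Segment and standardize every subject of a simulated study
#'
#' @param study a [simulate_study()] result.
#' @param rest_trim_seconds passed to [segment()].
#' @return named list: condition -> list of standardized per-subject
#'   [condition_dataset()]s.
#' @export
segment_study <- function(study, rest_trim_seconds = 4) {
  stopifnot(inherits(study, "connectivity_study"))
  per_subject <- lapply(study, function(s)
    lapply(segment(s$timeseries, s$schedule, rest_trim_seconds),
           standardize))
  conds <- unique(unlist(lapply(per_subject, names)))
  out <- lapply(conds, function(cond)
    lapply(per_subject, `[[`, cond))
  names(out) <- conds
  out
}
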