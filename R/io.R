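# Plain-text readers and writers for the pipeline's artifacts: subject
# time series and schedules as TSV, graphs as edge-list TSV and DOT,
# per-condition edge tables as TSV.

#' Write / read a subject's ROI time series as TSV
#'
#' One row per TR, one column per ROI, header line of ROI labels.
#'
#' @param ts a `roi_timeseries`.
#' @param path file path.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param subject_id identifier attached to the result.
#' @export
read_timeseries <- function(path, subject_id = basename(path)) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  structure(list(subject_id = subject_id, roi_labels = colnames(m),
                 values = m),
            class = "roi_timeseries")
}

#' Write / read a block schedule as TSV
#'
#' Three columns: `condition`, `onset_tr` (0-based), `n_trs` (half-open
#' segment length in TRs).  The TR duration travels as a `# tr_seconds=`
#' comment so round trips preserve it.
#'
#' @param schedule a `block_schedule`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "block_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_seconds=%g", attr(schedule, "tr_seconds")), con)
  utils::write.table(as.data.frame(schedule), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  first <- readLines(path, n = 1L)
  tr <- if (startsWith(first, "# tr_seconds="))
    as.numeric(sub("# tr_seconds=", "", first)) else 2
  sch <- utils::read.delim(path, comment.char = "#")
  structure(sch, class = c("block_schedule", "data.frame"),
            tr_seconds = tr,
            total_trs = if (nrow(sch))
              max(sch$onset_tr + sch$n_trs) else 0L)
}

#' Write a graph as an edge-list TSV
#'
#' Columns `source`, `target` and, when weights are supplied, `weight`.
#'
#' @param g a `dag` or `skeleton`.
#' @param path file path.
#' @param weights optional numeric vector named by `"source->target"`.
#' @export
write_edgelist <- function(g, path, weights = NULL) {
  df <- as.data.frame(g$edges)
  if (!is.null(weights))
    df$weight <- unname(weights[edge_key(df$source, df$target)])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @param nodes node labels for the reconstructed graph (defaults to the
#'   labels appearing in the file).
#' @param directed read as a `dag` (default) or `skeleton`.
#' @export
read_edgelist <- function(path, nodes = NULL, directed = TRUE) {
  df <- utils::read.delim(path, colClasses = "character")
  if (is.null(nodes)) nodes <- sort(unique(c(df$source, df$target)))
  e <- cbind(source = df$source, target = df$target)
  if (directed) dag(nodes, e) else skeleton(nodes, e)
}

#' Write a graph in DOT format
#'
#' @param g a `dag` (rendered with `->`) or `skeleton` (`--`).
#' @param path file path.
#' @param name graph name in the DOT header.
#' @export
write_dot <- function(g, path, name = "connectivity") {
  directed <- inherits(g, "dag")
  arrow <- if (directed) " -> " else " -- "
  lines <- c(paste0(if (directed) "digraph " else "graph ", name, " {"),
             paste0("  \"", g$nodes, "\";"),
             if (nrow(g$edges))
               paste0("  \"", g$edges[, 1L], "\"", arrow,
                      "\"", g$edges[, 2L], "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a condition's edge table as TSV
#'
#' Columns `source`, `target`, `direction_marker` (`forward` /
#' `reversed` / `unknown` relative to the sorted pair), `mean`, `sd`,
#' `n_subjects`.
#'
#' @param tab an [edge_table()].
#' @param path file path.
#' @param n_subjects subject count recorded in the output.
#' @export
write_edge_table <- function(tab, path, n_subjects = NA_integer_) {
  stopifnot(inherits(tab, "edge_table"))
  df <- data.frame(
    source = ifelse(tab$rel_dir >= 0, tab$node1, tab$node2),
    target = ifelse(tab$rel_dir >= 0, tab$node2, tab$node1),
    direction_marker = ifelse(!tab$dir_known, "unknown",
                              ifelse(tab$rel_dir >= 0, "forward",
                                     "reversed")),
    mean = round(tab$mean, 2L), sd = round(tab$sd, 2L),
    n_subjects = n_subjects)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
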