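#' Per-condition edge table
#'
#' One row per connection present in a condition, identified by the
#' unordered ROI pair (`node1 < node2` lexicographically).  `rel_dir` is
#' +1 when the connection points `node1 -> node2`, -1 for the reverse;
#' `dir_known` is `FALSE` for connections whose absolute direction is not
#' resolved (printed without an arrow), in which case `rel_dir` is still
#' meaningful *relative to the same row in other conditions*.
#'
#' @param condition condition label.
#' @param entries data frame with columns `node1`, `node2`, `rel_dir`,
#'   `mean`, `sd`, `dir_known`, and optionally `connection` — the
#'   identity a connection is tracked by across conditions.  It defaults
#'   to the unordered pair key; table transcriptions use the printed row
#'   label instead, because published tables occasionally print the two
#'   orientations of one pair as distinct connections.
#' @return An object of class `edge_table` (a data frame) with attribute
#'   `condition`.
#' @export
edge_table <- function(condition, entries) {
  need <- c("node1", "node2", "rel_dir", "mean", "sd", "dir_known")
  stopifnot(all(need %in% names(entries)))
  entries <- as.data.frame(entries)
  if (is.null(entries$connection))
    entries$connection <- if (nrow(entries))
      pair_key(entries$node1, entries$node2) else character(0)
  entries <- entries[c(need, "connection")]
  if (anyDuplicated(entries$connection))
    stop("more than one entry for the same connection")
  if (any(entries$node1 > entries$node2))
    stop("entries must have node1 < node2")
  structure(entries, condition = unname(condition),
            class = c("edge_table", "data.frame"))
}

#' Build an edge table from an oriented DAG and its coefficient summary
#'
#' @param condition condition label.
#' @param estimates an [estimate_edges()] result (its `source`/`target`
#'   give the oriented direction).
#' @return an [edge_table()].
#' @export
build_edge_table <- function(condition, estimates) {
  stopifnot(inherits(estimates, "edge_estimates"))
  node1 <- pmin(estimates$source, estimates$target)
  node2 <- pmax(estimates$source, estimates$target)
  edge_table(condition, data.frame(
    node1 = node1, node2 = node2,
    rel_dir = ifelse(estimates$source == node1, 1L, -1L),
    mean = estimates$mean, sd = estimates$sd,
    dir_known = TRUE))
}

# condition labels in printed-table column order
printed_columns <- function() {
  c(Intro1 = "prep1", `1-back` = "task1", Intro2 = "prep2",
    `2-back` = "task2", Intro3 = "prep3", `3-back` = "task3",
    Rest = "rest")
}

#' Load a transcribed connectivity table
#'
#' Reads a tab-separated transcription of a published connectivity table:
#' a header line `connection, Intro1, 1-back, Intro2, 2-back, Intro3,
#' 3-back, Rest`, then one row per connection.  The row label is
#' `"A->B"` (directed) or `"A-B"` (direction not resolved); each condition
#' cell is empty (connection absent) or `"mean (sd)"`, optionally prefixed
#' with `"<"` meaning the direction in that condition is the reverse of
#' the row label.
#'
#' @param path path to the TSV file.
#' @return named list of seven [edge_table()]s (`prep1`, `task1`, ...,
#'   `rest`).
#' @export
load_printed_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  split8 <- function(line) {
    f <- strsplit(paste0(line, "\tEND"), "\t", fixed = TRUE)[[1L]]
    f[-length(f)]
  }
  header <- split8(lines[1L])
  if (length(header) != 8L || !identical(header[-1L], names(printed_columns())))
    stop("unexpected header: ", lines[1L])
  conds <- printed_columns()
  rows <- lapply(lines[-1L], function(line) {
    f <- split8(line)
    if (length(f) != 8L)
      stop("malformed row (", length(f) - 1L, " cells, need 7): ", f[1L])
    f
  })
  labels <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(labels))
    stop("duplicate connection labels: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  parse_label <- function(lab) {
    if (grepl("->", lab, fixed = TRUE)) {
      ends <- strsplit(lab, "->", fixed = TRUE)[[1L]]
      c(ends, TRUE)
    } else {
      ends <- strsplit(lab, "-", fixed = TRUE)[[1L]]
      if (length(ends) != 2L) stop("cannot parse connection label: ", lab)
      c(ends, FALSE)
    }
  }
  cell_re <- "^(<\\s*)?(-?[0-9]*\\.?[0-9]+)\\s*\\((-?[0-9]*\\.?[0-9]+)\\)$"
  out <- lapply(seq_along(conds), function(ci) {
    entries <- list()
    for (r in seq_along(rows)) {
      cell <- trimws(rows[[r]][ci + 1L])
      if (!nzchar(cell)) next
      m <- regmatches(cell, regexec(cell_re, cell))[[1L]]
      if (!length(m))
        stop("cannot parse cell '", cell, "' in row ", labels[r])
      lab <- parse_label(labels[r])
      a <- lab[1L]; b <- lab[2L]; known <- as.logical(lab[3L])
      flipped <- nzchar(m[2L])
      # orientation of this cell relative to the sorted pair
      base <- if (a < b) 1L else -1L
      entries[[length(entries) + 1L]] <- data.frame(
        node1 = min(a, b), node2 = max(a, b),
        rel_dir = if (flipped) -base else base,
        mean = as.numeric(m[3L]), sd = as.numeric(m[4L]),
        dir_known = known, connection = labels[r])
    }
    entries <- if (length(entries)) do.call(rbind, entries) else
      data.frame(node1 = character(0), node2 = character(0),
                 rel_dir = integer(0), mean = numeric(0), sd = numeric(0),
                 dir_known = logical(0))
    edge_table(conds[ci], entries)
  })
  names(out) <- conds
  out
}

#' Classify connections into default and preparation-related sub-networks
#'
#' Pure set algebra over unordered ROI pairs across the seven condition
#' edge tables.  A connection is *default* when present in every
#' condition including rest; *preparation-related* for load k when
#' present during both the load-k preparation and the load-k task but
#' absent at rest; *preparation+rest-only* for load k when present during
#' load-k preparation and at rest but absent in all three task
#' conditions.  Presence is direction-blind (the same pair counts as
#' "common" even when its orientation flips between conditions);
#' `direction_variable` lists the pairs whose orientation differs across
#' the conditions where they are present.
#'
#' @param tables named list of exactly the seven condition
#'   [edge_table()]s (`prep1..3`, `task1..3`, `rest`).
#' @return An object of class `subnetwork_report`: list with
#'   `default_edges`, `prep_related` (per load), `prep_rest_only` (per
#'   load) and `direction_variable`, each a character vector of
#'   `"node1|node2"` pair keys, plus `nodes_covered` (nodes touched by
#'   default edges).
#' @export
classify_connections <- function(tables) {
  need <- condition_labels()
  missing <- setdiff(need, names(tables))
  if (length(missing))
    stop("missing condition label(s): ", paste(missing, collapse = ", "))
  # presence is tracked per connection identity; results are reported as
  # unordered pair keys (identical unless a table prints the two
  # orientations of one pair as separate connections)
  pres <- lapply(tables[need], function(tab)
    if (!nrow(tab)) character(0) else tab$connection)
  pair_of <- do.call(c, lapply(unname(tables[need]), function(tab)
    if (!nrow(tab)) NULL else
      stats::setNames(pair_key(tab$node1, tab$node2), tab$connection)))
  pair_of <- pair_of[!duplicated(names(pair_of))]
  as_pairs <- function(conns) {
    if (!length(conns)) return(character(0))
    sort(unique(unname(pair_of[conns])))
  }
  default_edges <- as_pairs(Reduce(intersect, pres))
  task_all <- unique(c(pres$task1, pres$task2, pres$task3))
  prep_related <- prep_rest_only <- list()
  for (k in 1:3) {
    pk <- pres[[paste0("prep", k)]]
    tk <- pres[[paste0("task", k)]]
    prep_related[[as.character(k)]] <-
      as_pairs(setdiff(intersect(pk, tk), pres$rest))
    prep_rest_only[[as.character(k)]] <-
      as_pairs(setdiff(intersect(pk, pres$rest), task_all))
  }
  dirs <- do.call(rbind, lapply(need, function(cond) {
    tab <- tables[[cond]]
    if (!nrow(tab)) return(NULL)
    data.frame(connection = tab$connection, rel_dir = tab$rel_dir)
  }))
  direction_variable <- if (is.null(dirs)) character(0) else
    as_pairs(names(which(tapply(dirs$rel_dir, dirs$connection,
                                function(d) length(unique(d)) > 1))))
  covered <- unique(unlist(strsplit(default_edges, "|", fixed = TRUE)))
  structure(list(default_edges = default_edges,
                 prep_related = prep_related,
                 prep_rest_only = prep_rest_only,
                 direction_variable = direction_variable,
                 nodes_covered = sort(covered)),
            class = "subnetwork_report")
}

#' @export
print.subnetwork_report <- function(x, ...) {
  cat(sprintf("Default sub-network: %d connections (touching %d nodes)\n",
              length(x$default_edges), length(x$nodes_covered)))
  for (k in names(x$prep_related))
    cat(sprintf("Preparation-related (%s-back): %d connection(s)%s\n",
                k, length(x$prep_related[[k]]),
                if (length(x$prep_related[[k]]))
                  paste0(" [", paste(x$prep_related[[k]], collapse = ", "), "]")
                else ""))
  for (k in names(x$prep_rest_only))
    if (length(x$prep_rest_only[[k]]))
      cat(sprintf("Preparation+rest only (%s-back): %s\n", k,
                  paste(x$prep_rest_only[[k]], collapse = ", ")))
  if (length(x$direction_variable))
    cat(sprintf("Direction varies across conditions for %d pair(s)\n",
                length(x$direction_variable)))
  invisible(x)
}

#' Compare a sub-network report against a generating graph set
#'
#' Precision and recall of the reported default and preparation-related
#' pair sets against the ground truth of a [sample_graph_set()].
#'
#' @param report a [classify_connections()] result.
#' @param truth the generating `condition_graph_set`.
#' @return An object of class `recovery_summary`: data frame with one row
#'   per class (`default`, `prep1..3`) and columns `precision`, `recall`,
#'   `n_true`, `n_reported`; recall is `NA` (not applicable) for classes
#'   with no true edges.
#' @export
compare_to_truth <- function(report, truth) {
  stopifnot(inherits(report, "subnetwork_report"),
            inherits(truth, "condition_graph_set"))
  all_nodes <- unique(unlist(strsplit(
    unlist(c(report$default_edges, report$prep_related,
             report$prep_rest_only)), "|", fixed = TRUE)))
  bad <- setdiff(all_nodes, truth$nodes)
  if (length(bad))
    stop("reported labels not in the ground truth: ",
         paste(bad, collapse = ", "))
  g_pairs <- function(cond) {
    e <- condition_graph(truth, cond)$edges
    if (!nrow(e)) character(0) else pair_key(e[, 1L], e[, 2L])
  }
  truth_sets <- list(default = Reduce(intersect,
                                      lapply(condition_labels(), g_pairs)))
  rest_pairs <- g_pairs("rest")
  for (k in 1:3)
    truth_sets[[paste0("prep", k)]] <-
      setdiff(intersect(g_pairs(paste0("prep", k)),
                        g_pairs(paste0("task", k))), rest_pairs)
  reported <- c(list(default = report$default_edges),
                stats::setNames(report$prep_related,
                                paste0("prep", names(report$prep_related))))
  rows <- lapply(names(truth_sets), function(cls) {
    tr <- truth_sets[[cls]]; rp <- reported[[cls]]
    data.frame(class = cls,
               precision = if (length(rp)) mean(rp %in% tr) else NA_real_,
               recall = if (length(tr)) mean(tr %in% rp) else NA_real_,
               n_true = length(tr), n_reported = length(rp))
  })
  structure(do.call(rbind, rows),
            class = c("recovery_summary", "data.frame"))
}
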