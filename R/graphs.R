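#' Directed acyclic graphs and skeletons over ROI labels
#'
#' A `dag` is a set of directed edges over named nodes with no directed
#' cycle; a `skeleton` is its undirected projection (adjacencies without
#' directions).  Edges are stored as a two-column character matrix.
#'
#' @param nodes character vector of node (ROI) labels.
#' @param edges two-column character matrix (or data.frame) of edges; for a
#'   `dag` the columns are (source, target), for a `skeleton` the pair is
#'   unordered and stored sorted.
#' @return An object of class `dag` or `skeleton`: a list with elements
#'   `nodes` and `edges`.
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' skeleton_of(g)
#' @export
dag <- function(nodes, edges = NULL) {
  edges <- as_edge_matrix(edges)
  check_edge_labels(nodes, edges)
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  g <- structure(list(nodes = as.character(nodes), edges = edges),
                 class = "dag")
  if (!is_acyclic(adjacency(g))) stop("edge set contains a directed cycle")
  g
}

#' @rdname dag
#' @export
skeleton <- function(nodes, edges = NULL) {
  edges <- as_edge_matrix(edges)
  check_edge_labels(nodes, edges)
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  edges <- unique(t(apply(edges, 1L, sort)))
  if (length(edges) == 0L) edges <- empty_edges()
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "skeleton")
}

empty_edges <- function() {
  matrix(character(), ncol = 2L,
         dimnames = list(NULL, c("source", "target")))
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L) return(empty_edges())
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  dimnames(edges) <- list(NULL, c("source", "target"))
  edges
}

check_edge_labels <- function(nodes, edges) {
  bad <- setdiff(unique(c(edges)), nodes)
  if (length(bad))
    stop("edge labels not among nodes: ", paste(bad, collapse = ", "))
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  invisible(TRUE)
}

#' Adjacency matrix of a graph
#'
#' @param g a `dag` or `skeleton`.
#' @return logical matrix `A` with `A[i, j]` `TRUE` when an edge i->j (dag)
#'   or adjacency i-j (skeleton, symmetric) is present.
#' @export
adjacency <- function(g) {
  n <- length(g$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    A[g$edges] <- TRUE
    if (inherits(g, "skeleton")) A[g$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

#' @export
print.dag <- function(x, ...) {
  cat(sprintf("DAG: %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L]), sep = "\n")
  invisible(x)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("Skeleton: %d nodes, %d adjacencies\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1L], " -- ", x$edges[, 2L]), sep = "\n")
  invisible(x)
}

# topological order of a logical adjacency matrix, or NULL if cyclic
topological_order <- function(A) {
  n <- nrow(A)
  indeg <- colSums(A)
  order <- integer(0)
  live <- rep(TRUE, n)
  while (length(order) < n) {
    src <- which(live & indeg == 0)
    if (!length(src)) return(NULL)
    v <- src[1L]
    order <- c(order, v)
    live[v] <- FALSE
    indeg <- indeg - A[v, ]
  }
  order
}

is_acyclic <- function(A) !is.null(topological_order(A))

# transitive reachability: R[i, j] TRUE iff a directed path i -> ... -> j
reachability <- function(A) {
  R <- A
  n <- nrow(A)
  for (k in seq_len(n))
    R <- R | (R[, k] %o% R[k, ])
  R
}

#' Undirected projection of a DAG
#'
#' @param g a `dag`.
#' @return the `skeleton` with the same nodes and one unordered pair per
#'   directed edge.
#' @export
skeleton_of <- function(g) {
  stopifnot(inherits(g, "dag"))
  skeleton(g$nodes, g$edges)
}

#' Test a skeleton for triangles
#'
#' A triangle ("triangulation") is a set of three mutually adjacent nodes.
#' Because the search targets causal structure among noisy regional
#' aggregates, triangles are treated as a symptom of spurious connections
#' and the structure search escalates its penalty until none remain.
#'
#' @param g a `skeleton` or `dag` (projected first).
#' @return `TRUE` if any three nodes are pairwise adjacent.
#' @seealso [find_first_nontriangular()]
#' @export
has_triangle <- function(g) {
  if (inherits(g, "dag")) g <- skeleton_of(g)
  stopifnot(inherits(g, "skeleton"))
  A <- adjacency(g)
  any((A %*% A) * A > 0)
}

# all triangles of a skeleton, as a character matrix with 3 columns
list_triangles <- function(g) {
  if (inherits(g, "dag")) g <- skeleton_of(g)
  A <- adjacency(g)
  n <- nrow(A)
  out <- NULL
  if (n >= 3L) {
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      ks <- which(A[i, ] & A[j, ])
      ks <- ks[ks > j]
      if (length(ks))
        out <- rbind(out, cbind(g$nodes[i], g$nodes[j], g$nodes[ks]))
    }
  }
  if (is.null(out)) out <- matrix(character(), ncol = 3L)
  out
}

edge_key <- function(source, target) paste(source, target, sep = "->")

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
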