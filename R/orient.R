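#' Anderson-Darling departure-from-normality statistic
#'
#' The sample is first standardized (mean 0, unit sample variance), then
#' scored against the standard normal distribution:
#' `A2 = -n - (1/n) * sum_{i=1..n} (2i - 1) * (ln F(z_(i)) +
#' ln(1 - F(z_(n+1-i))))` with `F` the standard normal CDF and `z_(i)` the
#' sorted standardized values.  CDF values are clipped to
#' `[1e-10, 1 - 1e-10]` so extreme observations cannot produce infinite
#' scores.  Larger values mean more non-Gaussian; the orientation stage
#' prefers the edge direction whose regression residuals score higher.
#'
#' @param sample numeric vector, length >= 8, non-constant.
#' @return An object of class `ad_score`: list with `a2` and `n`.
#' @examples
#' anderson_darling(runif(100))$a2  # systematically above gaussian samples
#' @export
anderson_darling <- function(sample) {
  n <- length(sample)
  if (n < 8L) stop("need at least 8 observations (got ", n, ")")
  s <- stats::sd(sample)
  if (!is.finite(s) || s == 0) stop("sample has zero variance")
  z <- sort((sample - mean(sample)) / s)
  F <- pmin(pmax(stats::pnorm(z), 1e-10), 1 - 1e-10)
  i <- seq_len(n)
  a2 <- -n - sum((2 * i - 1) * (log(F) + log(1 - rev(F)))) / n
  structure(list(a2 = a2, n = n), class = "ad_score")
}

#' @export
print.ad_score <- function(x, ...) {
  cat(sprintf("Anderson-Darling A2 = %.4f (n = %d)\n", x$a2, x$n))
  invisible(x)
}

# residuals of column j regressed (no intercept) on columns P
col_residuals <- function(X, j, P) {
  if (!length(P)) return(X[, j])
  stats::.lm.fit(X[, P, drop = FALSE], X[, j])$residuals
}

#' Orient every edge of a fixed skeleton by residual non-Gaussianity
#'
#' For each undirected adjacency \{X, Y\}, both candidate directions are
#' compared: under a direction, each endpoint is regressed on the parent
#' set implied locally by that choice (all its other adjacencies, plus the
#' other endpoint for the receiving node), and the direction score is the
#' sum over the two endpoints and over subjects of the Anderson-Darling
#' statistic of the regression residuals.  The residuals of an incorrectly
#' oriented linear model are closer to Gaussian than those of the correct
#' model when the structural innovations are non-Gaussian, so the
#' higher-scoring direction is kept (rule "pairwise-AD").  Orientation
#' never adds or removes adjacencies.  If the resulting directed graph is
#' cyclic, the edge with the smallest score margin on a cycle is flipped,
#' repeatedly, until the graph is acyclic.
#'
#' @param skel a `skeleton` (typically from [find_first_nontriangular()]).
#' @param datasets list of standardized [condition_dataset()]s, one per
#'   subject, whose ROI labels cover the skeleton's nodes.
#' @return a `dag` whose undirected projection equals `skel` exactly, with
#'   attribute `margins`: per-edge data frame of direction score margins
#'   and whether cycle repair flipped the edge.
#' @export
orient_edges <- function(skel, datasets) {
  stopifnot(inherits(skel, "skeleton"))
  if (inherits(datasets, "condition_dataset")) datasets <- list(datasets)
  mats <- lapply(datasets, function(ds) {
    stopifnot(inherits(ds, "condition_dataset"))
    if (!ds$standardized)
      stop("datasets must be standardized (see standardize())")
    ds$matrix
  })
  missing <- setdiff(skel$nodes, colnames(mats[[1L]]))
  if (length(missing))
    stop("skeleton nodes missing from datasets: ",
         paste(missing, collapse = ", "))
  nodes <- skel$nodes
  Adj <- adjacency(skel)
  nbrs <- lapply(nodes, function(v) nodes[Adj[v, ]])
  names(nbrs) <- nodes
  pooled_a2 <- function(node, parents) {
    sum(vapply(mats, function(X)
      anderson_darling(col_residuals(X, node, parents))$a2, numeric(1)))
  }
  # full-neighbourhood score per node, and leave-one-out scores per edge
  full <- vapply(nodes, function(v)
    if (length(nbrs[[v]])) pooled_a2(v, nbrs[[v]]) else NA_real_,
    numeric(1))
  E <- skel$edges
  if (nrow(E) == 0L)
    return(structure(dag(nodes), margins = data.frame()))
  ord <- order(E[, 1L], E[, 2L])
  E <- E[ord, , drop = FALSE]
  loo <- function(v, excl) pooled_a2(v, setdiff(nbrs[[v]], excl))
  src <- tgt <- character(nrow(E))
  margin <- numeric(nrow(E))
  for (r in seq_len(nrow(E))) {
    x <- E[r, 1L]; y <- E[r, 2L]
    s_xy <- loo(x, y) + full[y]   # x -> y: y keeps all parents incl. x
    s_yx <- full[x] + loo(y, x)   # y -> x
    if (s_xy >= s_yx) { src[r] <- x; tgt[r] <- y }
    else { src[r] <- y; tgt[r] <- x }
    margin[r] <- abs(s_xy - s_yx)
  }
  flipped <- rep(FALSE, nrow(E))
  idx <- function(v) match(v, nodes)
  repeat {
    A <- matrix(FALSE, length(nodes), length(nodes))
    A[cbind(idx(src), idx(tgt))] <- TRUE
    if (is_acyclic(A)) break
    R <- reachability(A)
    on_cycle <- R[cbind(idx(tgt), idx(src))]
    cand <- which(on_cycle & !flipped)
    if (!length(cand))
      stop("could not repair cycles by margin-ordered edge flips")
    f <- cand[order(margin[cand], src[cand], tgt[cand])][1L]
    tmp <- src[f]; src[f] <- tgt[f]; tgt[f] <- tmp
    flipped[f] <- TRUE
  }
  g <- dag(nodes, cbind(source = src, target = tgt))
  structure(g, margins = data.frame(source = src, target = tgt,
                                    margin = margin, flipped = flipped))
}
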