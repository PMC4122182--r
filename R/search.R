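#' Greedy equivalence search at a fixed penalty
#'
#' Score-based search over Markov equivalence classes of DAGs (CPDAGs)
#' for the structure maximizing the penalized Gaussian likelihood
#' averaged across per-subject datasets (see [local_bic()]).  Starting
#' from the empty graph, the forward phase repeatedly applies the single
#' best strictly score-improving edge insertion (evaluating, for every
#' non-adjacent ordered pair, the standard insertion operators with their
#' clique and semi-directed-path validity conditions) until no insertion
#' improves the score; the backward phase then repeatedly applies the
#' best strictly score-improving edge deletion until none improves.
#' After every move the graph is re-closed to the equivalence class
#' (consistent extension, v-structure pattern, Meek-rule closure), so the
#' search never commits to an arbitrary direction for an edge whose
#' orientation the data cannot determine — final directions are left to
#' the orientation stage.  The score is decomposable, so each operator
#' re-scores only the receiving node.
#'
#' Candidate moves of equal score are taken in a fixed deterministic
#' enumeration order (by target label, then source label, then operator
#' subset); improvements below `tol` count as no improvement.
#'
#' @param datasets list of standardized [condition_dataset()]s, one per
#'   subject.
#' @param c penalty discount.
#' @param tol strict-improvement threshold on the averaged score.
#' @param max_subset cap on the size of the insertion/deletion operator
#'   subsets (T and H) enumerated per candidate edge.
#' @return An object of class `search_result`: list with `dag` (a
#'   consistent extension of the equivalence class), `skeleton`,
#'   `c_used`, `score` (sum over nodes of averaged local scores) and
#'   `trace` (accepted moves with score deltas).
#' @examples
#' bench <- simulate_benchmark(n_vars = 6, n_subjects = 3,
#'                             n_timepoints = 150, edge_density = 0.25,
#'                             seed = 1)
#' res <- greedy_search(lapply(bench$datasets, standardize), c = 1)
#' res$skeleton
#' @export
greedy_search <- function(datasets, c = 1, tol = 1e-9, max_subset = 3L) {
  stats <- suffstats(datasets)
  labels <- stats[[1L]]$labels
  p <- length(labels)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  sc <- function(j, P) {
    key <- paste0(j, "|", paste(sort(P), collapse = ","))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- local_score_avg(stats, j, sort(P), c)
      cache[[key]] <- v
    }
    v
  }
  G <- matrix(FALSE, p, p)
  trace <- list()
  total_score <- function() {
    ext <- pdag_extension(G)
    sum(vapply(seq_len(p), function(j) sc(j, which(ext[, j])), numeric(1)))
  }
  note <- function(action, x, y, delta)
    trace[[length(trace) + 1L]] <<-
      data.frame(action = action, source = labels[x], target = labels[y],
                 delta = delta, score = total_score())
  node_order <- order(labels)
  # forward phase: best valid Insert(x, y, T)
  repeat {
    A <- G | t(G)
    cand <- list()
    for (y in node_order) {
      Ny <- pdag_neighbours(G, y)
      Pay <- pdag_parents(G, y)
      for (x in node_order) {
        if (x == y || A[x, y]) next
        NAyx <- Ny[A[x, Ny]]
        T0 <- Ny[!A[x, Ny]]
        for (Tset in subsets_upto(T0, max_subset)) {
          S <- c(NAyx, Tset)
          if (!is_clique_in(S, A)) next
          base <- unique(c(Pay, S))
          delta <- sc(y, c(base, x)) - sc(y, base)
          if (delta > tol)
            cand[[length(cand) + 1L]] <-
              list(x = x, y = y, Tset = Tset, S = S, delta = delta)
        }
      }
    }
    if (!length(cand)) break
    cand <- cand[order(-vapply(cand, `[[`, numeric(1), "delta"))]
    applied <- FALSE
    for (mv in cand) {
      if (!semi_directed_blocked(G, mv$y, mv$x, mv$S)) next
      G[mv$x, mv$y] <- TRUE
      G[mv$y, mv$Tset] <- FALSE        # orient T - y as T -> y
      G <- pdag_completion(G)
      note("insert", mv$x, mv$y, mv$delta)
      applied <- TRUE
      break
    }
    if (!applied) break
  }
  # backward phase: best valid Delete(x, y, H)
  repeat {
    A <- G | t(G)
    best <- NULL
    for (y in node_order) {
      Ny <- pdag_neighbours(G, y)
      Pay <- pdag_parents(G, y)
      for (x in node_order) {
        if (x == y || !A[x, y]) next
        if (G[y, x] && !G[x, y]) next    # only x -> y or x - y
        NAyx <- Ny[A[x, Ny]]
        for (H in subsets_upto(NAyx, max_subset)) {
          keep <- setdiff(NAyx, H)
          if (!is_clique_in(keep, A)) next
          base <- unique(c(setdiff(Pay, x), keep))
          delta <- sc(y, base) - sc(y, c(base, x))
          if (delta > tol && (is.null(best) || delta > best$delta + 1e-12))
            best <- list(x = x, y = y, H = H, delta = delta)
        }
      }
    }
    if (is.null(best)) break
    x <- best$x; y <- best$y
    G[x, y] <- G[y, x] <- FALSE
    for (h in best$H) {
      G[h, y] <- FALSE                   # orient y - h as y -> h
      if (G[h, x] && G[x, h]) G[h, x] <- FALSE   # and x - h as x -> h
    }
    G <- pdag_completion(G)
    note("delete", x, y, best$delta)
  }
  ext <- pdag_extension(G)
  idx <- which(ext, arr.ind = TRUE)
  g <- dag(labels, cbind(source = labels[idx[, 1L]],
                         target = labels[idx[, 2L]]))
  structure(list(dag = g,
                 skeleton = skeleton_of(g),
                 c_used = c,
                 score = total_score(),
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame()),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "Structure search: %d adjacencies at penalty discount c = %g (score %.3f)\n",
    nrow(x$skeleton$edges), x$c_used, x$score))
  invisible(x)
}

#' Penalty escalation to the first triangle-free graph
#'
#' Runs [greedy_search()] at increasing penalty discounts
#' `c_start, c_start + c_step, ...` and returns the first result whose
#' skeleton contains no triangle.  Triangles among noisy regional signals
#' are treated as symptoms of spurious connections, so a sparser penalty
#' is preferred over any triangulated solution.
#'
#' @inheritParams greedy_search
#' @param c_start,c_step,c_max escalation schedule (`c_start >= 1`,
#'   `c_step > 0`).
#' @return the accepted `search_result`, with `c_used` recording the
#'   penalty at which it was found.
#' @export
find_first_nontriangular <- function(datasets, c_start = 1, c_step = 1,
                                     c_max = 20, tol = 1e-9) {
  if (c_start < 1) stop("c_start must be >= 1")
  if (c_step <= 0) stop("c_step must be > 0")
  if (c_max < c_start) stop("c_max must be >= c_start")
  last <- NULL
  for (cc in seq(c_start, c_max, by = c_step)) {
    res <- greedy_search(datasets, c = cc)
    if (!has_triangle(res$skeleton)) return(res)
    last <- res
  }
  tri <- list_triangles(last$skeleton)
  stop("penalty escalation exhausted at c_max = ", c_max,
       "; residual triangles: ",
       paste(apply(tri, 1L, paste, collapse = "-"), collapse = ", "))
}
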