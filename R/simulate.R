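#' Innovation (error-term) specification for the linear SEM simulator
#'
#' Edge orientation by residual non-Gaussianity is only informative when
#' the structural innovations are non-Gaussian, so the default family is
#' uniform (strongly sub-Gaussian, excess kurtosis -1.2).  `laplace` and
#' `exponential-symmetrized` give super-Gaussian alternatives (excess
#' kurtosis 3); `gaussian` is provided for negative-control experiments
#' where orientation is expected to be uninformative.
#'
#' @param family one of `"uniform"`, `"laplace"`,
#'   `"exponential-symmetrized"`, `"gaussian"`.
#' @param scale standard deviation of the innovations (> 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(family = c("uniform", "laplace",
                                  "exponential-symmetrized", "gaussian"),
                       scale = 1) {
  family <- match.arg(family)
  if (scale <= 0) stop("scale must be > 0")
  structure(list(family = family, scale = scale), class = "noise_spec")
}

# n x p matrix of i.i.d. innovations with sd = spec$scale
draw_noise <- function(spec, n, p) {
  m <- n * p
  x <- switch(spec$family,
    uniform = stats::runif(m, -sqrt(3), sqrt(3)),
    laplace = stats::rexp(m, rate = sqrt(2)) *
      sample(c(-1, 1), m, replace = TRUE),
    `exponential-symmetrized` = {
      e <- stats::rexp(m) / sqrt(2)
      s <- sample(c(-1, 1), m, replace = TRUE)
      e * s
    },
    gaussian = stats::rnorm(m)
  )
  matrix(x * spec$scale, n, p)
}

# sample a DAG on `nodes` whose skeleton is triangle-free, edges oriented
# along a fixed topological order; errors when n_edges exceeds the
# triangle-free bound or sampling cannot place all edges
sample_triangle_free_edges <- function(nodes, n_edges, order,
                                       forbidden_pairs = character(0),
                                       base_adj = NULL) {
  n <- length(nodes)
  if (n_edges == 0L) return(empty_edges())
  max_edges <- floor(n^2 / 4)  # Mantel bound for triangle-free graphs
  if (n_edges > n * (n - 1) / 2 || n_edges > max_edges)
    stop("requested ", n_edges, " edges exceeds the triangle-free bound (",
         min(max_edges, n * (n - 1) / 2), ") on ", n, " nodes")
  A <- if (is.null(base_adj)) matrix(FALSE, n, n) else base_adj  # undirected
  cand <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  # order positions: earlier in `order` is upstream
  pos <- integer(n); pos[order] <- seq_len(n)
  keys <- pair_key(nodes[cand[, 1L]], nodes[cand[, 2L]])
  cand <- cand[!(keys %in% forbidden_pairs) &
                 !A[cand], , drop = FALSE]
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  picked <- matrix(integer(), ncol = 2L)
  r <- 1L
  while (nrow(picked) < n_edges && r <= nrow(cand)) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    # adding i-j forms a triangle iff some k is adjacent to both
    if (!any(A[i, ] & A[j, ])) {
      A[i, j] <- A[j, i] <- TRUE
      picked <- rbind(picked, c(i, j))
    }
    r <- r + 1L
  }
  if (nrow(picked) < n_edges)
    stop("could not place ", n_edges,
         " triangle-free edges; graph too dense, try fewer edges")
  src <- ifelse(pos[picked[, 1L]] < pos[picked[, 2L]],
                picked[, 1L], picked[, 2L])
  tgt <- ifelse(pos[picked[, 1L]] < pos[picked[, 2L]],
                picked[, 2L], picked[, 1L])
  cbind(source = nodes[src], target = nodes[tgt])
}

#' Sample a condition-specific ground-truth graph set
#'
#' Builds the ground truth a multi-condition connectivity experiment is
#' simulated from: a "default" edge set shared by all seven conditions
#' (three preparation, three task, rest) plus condition-specific extra
#' edges.  Under the `"paired"` scenario the extras of load k are identical
#' for `prepk` and `taskk` and absent at rest — exactly the structure the
#' sub-network classifier is meant to recover.  All edges are oriented
#' along one hidden topological order, so every condition graph is acyclic,
#' and each condition skeleton is kept triangle-free (the structure search
#' escalates its penalty until triangle-free, so a triangulated truth
#' would be unrecoverable by design).
#'
#' Defaults mirror the reported Increase-network structure: 18 ROIs,
#' 11 default connections and 1/2/5 preparation-related connections for
#' loads 1/2/3.
#'
#' @param nodes node labels, or a count (labelled `ROI01`, ...).
#' @param n_default_edges number of default (all-condition) edges.
#' @param n_extra_per_load length-3 count of extra edges for loads 1..3.
#' @param n_rest_extra extra rest-only edges (disjoint from load extras).
#' @param weight_range range of path-coefficient magnitudes (standardized
#'   scale); drawn uniformly, positive.
#' @param scenario `"paired"`: load-k extras shared by prep and task and
#'   excluded from rest.
#' @param seed RNG seed.
#' @return An object of class `condition_graph_set` with elements `nodes`,
#'   `default_edges`, `extra_edges` (per condition), `weights` (per
#'   condition, named by `"source->target"`).
#' @export
sample_graph_set <- function(nodes = 18,
                             n_default_edges = 11,
                             n_extra_per_load = c(1, 2, 5),
                             n_rest_extra = 0,
                             weight_range = c(0.5, 0.9),
                             scenario = "paired",
                             seed = NULL) {
  if (is.numeric(nodes) && length(nodes) == 1L)
    nodes <- sprintf("ROI%02d", seq_len(nodes))
  nodes <- as.character(nodes)
  scenario <- match.arg(scenario, "paired")
  stopifnot(length(n_extra_per_load) == 3L)
  with_seed(seed, {
    ord <- sample.int(length(nodes))
    default_edges <- sample_triangle_free_edges(nodes, n_default_edges, ord)
    default_pairs <- pair_key(default_edges[, 1L], default_edges[, 2L])
    default_adj <- adjacency(skeleton(nodes, default_edges))
    extra <- list()
    load_pairs <- character(0)
    for (k in 1:3) {
      ek <- sample_triangle_free_edges(
        nodes, n_extra_per_load[k], ord,
        forbidden_pairs = default_pairs, base_adj = default_adj)
      extra[[paste0("prep", k)]] <- ek
      extra[[paste0("task", k)]] <- ek
      load_pairs <- union(load_pairs,
                          if (nrow(ek)) pair_key(ek[, 1L], ek[, 2L]))
    }
    extra[["rest"]] <- sample_triangle_free_edges(
      nodes, n_rest_extra, ord,
      forbidden_pairs = c(default_pairs, load_pairs),
      base_adj = default_adj)
    w_default <- stats::runif(nrow(default_edges),
                              weight_range[1L], weight_range[2L])
    names(w_default) <- edge_key(default_edges[, 1L], default_edges[, 2L])
    weights <- list()
    for (cond in condition_labels()) {
      ex <- extra[[cond]]
      w_ex <- stats::runif(NROW(ex), weight_range[1L], weight_range[2L])
      if (NROW(ex)) names(w_ex) <- edge_key(ex[, 1L], ex[, 2L])
      weights[[cond]] <- c(w_default, w_ex)
    }
    structure(list(nodes = nodes,
                   default_edges = default_edges,
                   extra_edges = extra,
                   weights = weights),
              class = "condition_graph_set")
  })
}

#' Condition graph of a graph set
#'
#' @param graphs a `condition_graph_set`.
#' @param condition one of `prep1..3`, `task1..3`, `rest`.
#' @return the condition's `dag` (default plus condition-specific edges).
#' @export
condition_graph <- function(graphs, condition) {
  stopifnot(inherits(graphs, "condition_graph_set"))
  condition <- match.arg(condition, condition_labels())
  dag(graphs$nodes,
      rbind(graphs$default_edges, graphs$extra_edges[[condition]]))
}

# p x p coefficient matrix B with B[source, target] = path weight
weight_matrix <- function(graphs, condition, jitter_mult = NULL) {
  g <- condition_graph(graphs, condition)
  w <- graphs$weights[[condition]]
  B <- matrix(0, length(graphs$nodes), length(graphs$nodes),
              dimnames = list(graphs$nodes, graphs$nodes))
  if (nrow(g$edges)) {
    keys <- edge_key(g$edges[, 1L], g$edges[, 2L])
    wv <- w[keys]
    if (!is.null(jitter_mult)) wv <- wv * jitter_mult[keys]
    B[g$edges] <- wv
  }
  B
}

# draw n i.i.d. SEM observations given coefficient matrix B (B[p, c]);
# x_j = sum_p B[p, j] x_p + e_j, evaluated in topological order
sem_rows <- function(B, noise, n) {
  ord <- topological_order(B != 0)
  if (is.null(ord)) stop("coefficient matrix encodes a cyclic graph")
  X <- draw_noise(noise, n, ncol(B))
  for (j in ord) {
    pa <- which(B[, j] != 0)
    if (length(pa))
      X[, j] <- X[, j] + X[, pa, drop = FALSE] %*% B[pa, j]
  }
  X
}

#' Simulate one subject's ROI time series
#'
#' Within each schedule segment, rows are i.i.d. draws from the linear SEM
#' of that segment's condition; per-subject variability is modelled by a
#' multiplicative jitter on every path coefficient, drawn once per subject
#' per edge and applied in all conditions.  No hemodynamic convolution is
#' applied: the downstream analysis consumes raw segment samples.  An
#' optional AR(1) coloring (`ar1 > 0`) is available for robustness
#' experiments only.
#'
#' @param graphs a [sample_graph_set()] result.
#' @param schedule a [make_schedule()] result.
#' @param noise a [noise_spec()].
#' @param subject_jitter half-width of the uniform multiplicative
#'   coefficient jitter (0.1 = +/-10 percent).
#' @param seed RNG seed (per subject).
#' @param subject_id identifier carried into the output.
#' @param ar1 optional AR(1) coefficient applied within segments.
#' @return An object of class `roi_timeseries`: list with `subject_id`,
#'   `roi_labels` and `values` (TRs x ROIs matrix).
#' @export
simulate_subject <- function(graphs, schedule, noise = noise_spec(),
                             subject_jitter = 0.1, seed = NULL,
                             subject_id = "sub01", ar1 = 0) {
  stopifnot(inherits(graphs, "condition_graph_set"),
            inherits(schedule, "block_schedule"),
            inherits(noise, "noise_spec"))
  if (nrow(schedule) == 0L) stop("schedule is empty")
  with_seed(seed, {
    all_keys <- unique(unlist(lapply(graphs$weights, names)))
    mult <- 1 + stats::runif(length(all_keys), -subject_jitter, subject_jitter)
    names(mult) <- all_keys
    Bs <- lapply(condition_labels(), function(cond)
      weight_matrix(graphs, cond, jitter_mult = mult))
    names(Bs) <- condition_labels()
    chunks <- vector("list", nrow(schedule))
    for (r in seq_len(nrow(schedule))) {
      X <- sem_rows(Bs[[schedule$condition[r]]], noise, schedule$n_trs[r])
      if (ar1 > 0 && nrow(X) > 1L)
        for (t in 2:nrow(X)) X[t, ] <- ar1 * X[t - 1L, ] + X[t, ]
      chunks[[r]] <- X
    }
    values <- do.call(rbind, chunks)
    colnames(values) <- graphs$nodes
    structure(list(subject_id = subject_id,
                   roi_labels = graphs$nodes,
                   values = values),
              class = "roi_timeseries")
  })
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: subject %s, %d TRs x %d ROIs\n",
              x$subject_id, nrow(x$values), length(x$roi_labels)))
  invisible(x)
}

#' Simulate a multi-subject study
#'
#' Each subject gets their own randomized block order (schedules differ
#' across subjects, as in a counterbalanced experiment) and their own
#' coefficient jitter; all subjects share the ground-truth graph set.
#'
#' @inheritParams simulate_subject
#' @param params a [schedule_params()] object; its seed is offset per
#'   subject.
#' @param n_subjects number of subjects (study default 16).
#' @return list of per-subject lists with elements `timeseries` and
#'   `schedule`, plus attribute `graphs`.
#' @export
simulate_study <- function(graphs, params = schedule_params(),
                           n_subjects = 16, noise = noise_spec(),
                           subject_jitter = 0.1, seed = 1L) {
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p_i <- params
    p_i$seed <- seed * 1000L + i
    sch <- make_schedule(p_i)
    ts <- simulate_subject(graphs, sch, noise = noise,
                           subject_jitter = subject_jitter,
                           seed = seed * 1000L + 500L + i,
                           subject_id = sprintf("sub%02d", i))
    subjects[[i]] <- list(timeseries = ts, schedule = sch)
  }
  structure(subjects, graphs = graphs, class = "connectivity_study")
}

#' Simulate a single-condition recovery benchmark
#'
#' Generates one shared triangle-free truth DAG over `n_vars` variables and
#' one i.i.d. SEM dataset per subject with per-subject coefficient jitter —
#' the standard setting for measuring adjacency recall of the structure
#' search and orientation accuracy of the non-Gaussianity stage.
#'
#' @param n_vars number of variables (>= 2).
#' @param n_subjects number of independent subject datasets.
#' @param n_timepoints rows per subject dataset.
#' @param edge_density fraction of the `n_vars * (n_vars - 1) / 2` pairs
#'   carrying an edge; must yield at least one edge.
#' @param noise a [noise_spec()].
#' @param weight_range path-coefficient magnitude range.
#' @param subject_jitter multiplicative coefficient jitter half-width.
#' @param seed RNG seed.
#' @return list with `datasets` (unstandardized [condition_dataset()]s),
#'   `graph` (truth `dag`) and `weights` (named coefficient vector).
#' @export
simulate_benchmark <- function(n_vars = 50, n_subjects = 10,
                               n_timepoints = 200, edge_density = 0.05,
                               noise = noise_spec(),
                               weight_range = c(0.5, 0.9),
                               subject_jitter = 0.1, seed = NULL) {
  if (n_vars < 2) stop("n_vars must be >= 2")
  n_edges <- round(edge_density * n_vars * (n_vars - 1) / 2)
  if (n_edges < 1) stop("edge_density ", edge_density,
                        " yields fewer than one edge on ", n_vars, " nodes")
  nodes <- sprintf("V%02d", seq_len(n_vars))
  with_seed(seed, {
    ord <- sample.int(n_vars)
    edges <- sample_triangle_free_edges(nodes, n_edges, ord)
    w <- stats::runif(n_edges, weight_range[1L], weight_range[2L])
    names(w) <- edge_key(edges[, 1L], edges[, 2L])
    g <- dag(nodes, edges)
    B0 <- matrix(0, n_vars, n_vars, dimnames = list(nodes, nodes))
    B0[edges] <- w
    datasets <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      B <- B0
      B[edges] <- w * (1 + stats::runif(n_edges, -subject_jitter,
                                        subject_jitter))
      X <- sem_rows(B, noise, n_timepoints)
      colnames(X) <- nodes
      datasets[[i]] <- condition_dataset(X, condition = "benchmark",
                                         subject_id = sprintf("sub%02d", i))
    }
    list(datasets = datasets, graph = g, weights = w)
  })
}
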