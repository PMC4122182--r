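# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package (lm/QR regressions and
# brute-force enumeration instead of covariance algebra and greedy moves).

# standardized dataset from a coefficient matrix B (B[p, c]), uniform
# innovations with per-column sd `scales`
sem_dataset <- function(B, n, subject = "s1", scales = rep(1, ncol(B)),
                        condition = "x") {
  p <- ncol(B)
  E <- matrix(runif(n * p, -sqrt(3), sqrt(3)), n, p)
  E <- sweep(E, 2L, scales, "*")
  X <- E
  remaining <- seq_len(p)
  done <- logical(p)
  while (any(!done)) {
    for (j in remaining[!done[remaining]]) {
      pa <- which(B[, j] != 0)
      if (all(done[pa]) || !length(pa)) {
        if (length(pa)) X[, j] <- X[, j] + X[, pa, drop = FALSE] %*% B[pa, j]
        done[j] <- TRUE
      }
    }
  }
  colnames(X) <- colnames(B)
  standardize(condition_dataset(X, condition, subject))
}

# p-node chain/collider helpers
named_B <- function(labels) {
  B <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  B
}

# brute-force enumeration of all DAGs on the given nodes: each unordered
# pair is absent, forward, or backward
enumerate_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- utils::combn(p, 2)
  states <- expand.grid(rep(list(0:2), ncol(pairs)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    A <- matrix(FALSE, p, p)
    for (k in seq_len(ncol(pairs))) {
      s <- states[r, k]
      if (s == 1) A[pairs[1, k], pairs[2, k]] <- TRUE
      if (s == 2) A[pairs[2, k], pairs[1, k]] <- TRUE
    }
    # acyclicity by repeated sink removal
    M <- A
    acyclic <- TRUE
    live <- rep(TRUE, p)
    while (any(live)) {
      sinks <- which(live & rowSums(M[, live, drop = FALSE]) == 0)
      if (!length(sinks)) { acyclic <- FALSE; break }
      live[sinks[1]] <- FALSE
      M[sinks[1], ] <- FALSE
    }
    if (acyclic) {
      dimnames(A) <- list(nodes, nodes)
      out[[length(out) + 1L]] <- A
    }
  }
  out
}

# lm-based penalized score of a whole DAG (adjacency matrix), averaged
# across standardized datasets
oracle_graph_score <- function(A, datasets, c = 1) {
  nodes <- rownames(A)
  per_ds <- vapply(datasets, function(ds) {
    X <- ds$matrix
    n <- nrow(X)
    tot <- 0
    for (v in nodes) {
      pa <- nodes[A[, v]]
      res <- if (length(pa))
        stats::lm.fit(X[, pa, drop = FALSE], X[, v])$residuals
      else X[, v]
      sigma2 <- mean(res^2)
      tot <- tot + (-n * log(sigma2) - c * (length(pa) + 1) * log(n))
    }
    tot
  }, numeric(1))
  mean(per_ds)
}

# skeleton pair keys and v-structure keys of an adjacency matrix
skeleton_keys <- function(A) {
  idx <- which((A | t(A)) & upper.tri(A), arr.ind = TRUE)
  nodes <- rownames(A)
  sort(paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "|"))
}
vstructure_keys <- function(A) {
  nodes <- rownames(A)
  out <- character(0)
  for (ch in seq_len(nrow(A))) {
    pars <- which(A[, ch])
    if (length(pars) >= 2)
      for (i in seq_along(pars)[-length(pars)])
        for (j in (i + 1):length(pars))
          if (!A[pars[i], pars[j]] && !A[pars[j], pars[i]])
            out <- c(out, paste(sort(nodes[c(pars[i], pars[j])])[1],
                                sort(nodes[c(pars[i], pars[j])])[2],
                                nodes[ch]))
  }
  sort(out)
}

increase_table_path <- function() {
  system.file("extdata", "table_increase.tsv", package = "effconn",
              mustWork = TRUE)
}
decrease_table_path <- function() {
  system.file("extdata", "table_decrease.tsv", package = "effconn",
              mustWork = TRUE)
}

pair_keys_of <- function(skel) {
  if (!nrow(skel$edges)) return(character(0))
  paste(skel$edges[, 1], skel$edges[, 2], sep = "|")
}
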