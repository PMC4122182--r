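# Partially directed graph (PDAG/CPDAG) machinery for the equivalence-class
# search.  A graph is a logical matrix G: a directed edge i -> j has
# G[i, j] TRUE and G[j, i] FALSE; an undirected edge i - j has both TRUE.

pdag_parents <- function(G, y) which(G[, y] & !G[y, ])
pdag_neighbours <- function(G, y) which(G[, y] & G[y, ])

is_clique_in <- function(S, A) {
  if (length(S) < 2L) return(TRUE)
  all(A[S, S][upper.tri(matrix(TRUE, length(S), length(S)))])
}

# TRUE iff every semi-directed path y ~> x passes through S (i.e. x is
# unreachable from y when nodes in S block traversal)
semi_directed_blocked <- function(G, y, x, S) {
  vis <- rep(FALSE, nrow(G))
  stack <- y
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in which(G[v, ])) {
      if (w == x) return(FALSE)
      if (!vis[w] && !(w %in% S)) {
        vis[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  TRUE
}

# Dor & Tarsi: orient the undirected edges of a PDAG into a DAG consistent
# with its directed edges and v-structures; errors if none exists
pdag_extension <- function(G) {
  p <- nrow(G)
  res <- G & !t(G)            # keep existing directed edges
  alive <- rep(TRUE, p)
  Gw <- G
  while (any(alive)) {
    found <- FALSE
    for (x in which(alive)) {
      if (any(Gw[x, ] & !Gw[, x])) next        # has directed out-edge
      adjx <- which(Gw[x, ] | Gw[, x])
      unx <- which(Gw[x, ] & Gw[, x])
      ok <- TRUE
      for (y in unx) {
        others <- setdiff(adjx, y)
        if (length(others) && !all(Gw[y, others] | Gw[others, y])) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      res[unx, x] <- TRUE                      # orient y -> x (x is a sink)
      alive[x] <- FALSE
      Gw[x, ] <- Gw[, x] <- FALSE
      found <- TRUE
      break
    }
    if (!found) stop("PDAG admits no consistent extension")
  }
  res
}

# one Meek-rule orientation of an undirected edge, or NULL at closure
meek_step <- function(G) {
  Dm <- G & !t(G)
  U <- G & t(G)
  A <- G | t(G)
  und <- which(U & upper.tri(U), arr.ind = TRUE)
  for (r in seq_len(nrow(und))) {
    for (swap in 1:2) {
      b <- if (swap == 1L) und[r, 1L] else und[r, 2L]
      cc <- if (swap == 1L) und[r, 2L] else und[r, 1L]
      # R1: a -> b, b - c, a not adjacent to c  =>  b -> c
      if (any(Dm[, b] & !A[, cc] & seq_len(nrow(G)) != cc))
        return(c(b, cc))
      # R2: b -> k -> c with b - c  =>  b -> c
      if (any(Dm[b, ] & Dm[, cc]))
        return(c(b, cc))
      # R3: b - k1, b - k2, k1 -> c, k2 -> c, k1 not adjacent k2  =>  b -> c
      ks <- which(U[b, ] & Dm[, cc])
      if (length(ks) >= 2L && !is_clique_in(ks, A))
        return(c(b, cc))
    }
  }
  NULL
}

# CPDAG (pattern) of a DAG: v-structures directed, Meek closure applied
cpdag_from_dag <- function(Ad) {
  p <- nrow(Ad)
  A <- Ad | t(Ad)
  G <- A
  for (ch in seq_len(p)) {
    pars <- which(Ad[, ch])
    if (length(pars) >= 2L)
      for (i in seq_along(pars)[-length(pars)])
        for (j in (i + 1L):length(pars))
          if (!A[pars[i], pars[j]])
            G[ch, c(pars[i], pars[j])] <- FALSE
  }
  repeat {
    mv <- meek_step(G)
    if (is.null(mv)) break
    G[mv[2L], mv[1L]] <- FALSE
  }
  G
}

# re-close a PDAG produced by an Insert/Delete operator into its CPDAG
pdag_completion <- function(G) cpdag_from_dag(pdag_extension(G))

subsets_upto <- function(S, k) {
  out <- list(integer(0))
  # index through seq_along: combn(x, m) on a length-1 numeric x would
  # enumerate seq_len(x) instead of the single element
  for (m in seq_len(min(length(S), k)))
    out <- c(out, lapply(utils::combn(seq_along(S), m, simplify = FALSE),
                         function(i) S[i]))
  out
}
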