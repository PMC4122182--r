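chain_datasets <- function(n_subjects = 10, n = 500, beta = 0.9) {
  labels <- c("A", "B", "C")
  lapply(seq_len(n_subjects), function(i) {
    B <- named_B(labels)
    B["A", "B"] <- beta; B["B", "C"] <- beta
    sem_dataset(B, n, sprintf("s%02d", i))
  })
}

test_that("chain data recover the chain skeleton, matching exhaustive search", {
  set.seed(10)
  dss <- chain_datasets()
  res <- greedy_search(dss, c = 1)
  found <- pair_keys_of(res$skeleton)
  expect_setequal(found, c("A|B", "B|C"))
  # oracle: enumerate all 25 DAGs on 3 nodes, score each, compare skeletons
  dags <- enumerate_dags(c("A", "B", "C"))
  expect_length(dags, 25L)
  scores <- vapply(dags, oracle_graph_score, numeric(1), datasets = dss)
  best <- dags[[which.max(scores)]]
  expect_setequal(found, skeleton_keys(best))
})

test_that("greedy search matches exhaustive enumeration on 4-node problems", {
  set.seed(11)
  dags4 <- enumerate_dags(c("A", "B", "C", "D"))
  reps <- 20L
  agree <- 0L
  for (r in seq_len(reps)) {
    labels <- c("A", "B", "C", "D")
    B <- named_B(labels)
    ord <- sample(4)                    # orient along a random order
    pairs <- utils::combn(4, 2)[, sample(6, 3)]
    for (k in 1:3) {
      ij <- pairs[, k]
      ij <- ij[order(match(ij, ord))]
      B[labels[ij[1]], labels[ij[2]]] <- runif(1, 0.5, 0.9)
    }
    dss <- lapply(1:3, function(i) sem_dataset(B, 1000, sprintf("s%d", i)))
    res <- greedy_search(dss, c = 1)
    scores <- vapply(dags4, oracle_graph_score, numeric(1), datasets = dss)
    best <- dags4[[which.max(scores)]]
    if (setequal(pair_keys_of(res$skeleton), skeleton_keys(best)))
      agree <- agree + 1L
  }
  expect_gte(agree / reps, 0.95)
})

test_that("independent columns give an empty graph in nearly all replicates", {
  set.seed(12)
  reps <- 20L
  empties <- 0L
  for (r in seq_len(reps)) {
    dss <- lapply(1:5, function(i) {
      m <- matrix(runif(500 * 4, -1, 1), 500, 4,
                  dimnames = list(NULL, c("A", "B", "C", "D")))
      standardize(condition_dataset(m, "x", sprintf("s%d", i)))
    })
    res <- greedy_search(dss, c = 2)
    if (nrow(res$skeleton$edges) == 0L) empties <- empties + 1L
  }
  expect_gte(empties / reps, 0.95)
})

test_that("the search trace is strictly increasing and the result reproducible", {
  set.seed(13)
  dss <- chain_datasets(n_subjects = 4, n = 300)
  res <- greedy_search(dss, c = 1)
  expect_true(all(diff(res$trace$score) > 0))
  expect_true(all(res$trace$delta > 0))
  res2 <- greedy_search(dss, c = 1)
  expect_identical(res$dag$edges, res2$dag$edges)
})

test_that("triangle detection follows its definition", {
  nodes <- c("A", "B", "C", "D")
  expect_true(has_triangle(skeleton(nodes, rbind(c("A", "B"), c("B", "C"),
                                                 c("A", "C")))))
  expect_false(has_triangle(skeleton(nodes, rbind(c("A", "B"), c("B", "C")))))
  expect_false(has_triangle(skeleton(nodes)))
})

test_that("returned edge count is non-increasing in the penalty discount", {
  set.seed(14)
  bench <- simulate_benchmark(n_vars = 12, n_subjects = 4,
                              n_timepoints = 150, edge_density = 0.15,
                              seed = 15)
  dss <- lapply(bench$datasets, standardize)
  sizes <- vapply(c(1, 2, 4, 8), function(cc)
    nrow(greedy_search(dss, c = cc)$skeleton$edges), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("penalty escalation stops at the first triangle-free skeleton", {
  set.seed(16)
  # strong 3-clique: A -> B, A -> C, B -> C all present.  The weakest
  # signal is the A-B partial correlation given C (~0.08 here), so the
  # sample must be long enough for its likelihood gain (~ n * 0.007) to
  # clear the c = 1 penalty (log n) and produce the triangle.
  labels <- c("A", "B", "C")
  B <- named_B(labels)
  B["A", "B"] <- 0.8; B["A", "C"] <- 0.8; B["B", "C"] <- 0.8
  dss <- lapply(1:6, function(i) sem_dataset(B, 3000, sprintf("s%d", i)))
  r1 <- greedy_search(dss, c = 1)
  expect_true(has_triangle(r1$skeleton))
  res <- find_first_nontriangular(dss, c_max = 200, c_step = 5)
  expect_false(has_triangle(res$skeleton))
  expect_gt(res$c_used, 1)
  # already triangle-free data accept the first penalty
  chain <- chain_datasets(n_subjects = 4, n = 300)
  expect_equal(find_first_nontriangular(chain)$c_used, 1)
  # an exhausted schedule reports the residual triangles
  expect_error(find_first_nontriangular(dss, c_max = 1), "triangles: A-B-C")
})
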