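test_that("graph sets respect requested counts and the paired scenario", {
  gs <- sample_graph_set(nodes = 18, n_default_edges = 11,
                         n_extra_per_load = c(1, 2, 5), seed = 3)
  expect_equal(nrow(gs$default_edges), 11L)
  # intersection of all 7 condition graphs is exactly the default set
  keys <- lapply(effconn:::condition_labels(), function(cond) {
    e <- condition_graph(gs, cond)$edges
    paste(e[, 1], e[, 2], sep = "->")
  })
  common <- Reduce(intersect, keys)
  expect_setequal(common,
                  paste(gs$default_edges[, 1], gs$default_edges[, 2],
                        sep = "->"))
  # paired scenario: prep_k and task_k extras identical, absent at rest
  for (k in 1:3) {
    expect_identical(gs$extra_edges[[paste0("prep", k)]],
                     gs$extra_edges[[paste0("task", k)]])
    expect_equal(nrow(gs$extra_edges[[paste0("prep", k)]]), c(1L, 2L, 5L)[k])
  }
  expect_equal(nrow(gs$extra_edges$rest), 0L)
})

test_that("every condition graph is acyclic and triangle-free", {
  for (seed in c(1, 2, 3)) {
    gs <- sample_graph_set(seed = seed)
    for (cond in effconn:::condition_labels()) {
      g <- condition_graph(gs, cond)     # dag() validates acyclicity
      expect_s3_class(g, "dag")
      expect_false(has_triangle(skeleton_of(g)))
    }
  }
})

test_that("infeasible edge counts are rejected with the bound", {
  expect_error(sample_graph_set(nodes = 4, n_default_edges = 7, seed = 1),
               "bound")
})

test_that("zero extras give identical condition graphs", {
  gs <- sample_graph_set(n_extra_per_load = c(0, 0, 0), seed = 5)
  base <- condition_graph(gs, "rest")$edges
  for (cond in effconn:::condition_labels())
    expect_identical(condition_graph(gs, cond)$edges, base)
})

test_that("SEM simulation matches its analytic second moments", {
  # closed form: cov = (I - B)^-T Sigma_e (I - B)^-1
  labels <- sprintf("N%d", 1:5)
  gs <- sample_graph_set(nodes = labels, n_default_edges = 5,
                         n_extra_per_load = c(0, 0, 0), seed = 8)
  B <- effconn:::weight_matrix(gs, "rest")
  n <- 8000
  sch <- structure(data.frame(condition = "rest", onset_tr = 0L,
                              n_trs = as.integer(n)),
                   class = c("block_schedule", "data.frame"),
                   tr_seconds = 2, total_trs = as.integer(n))
  ts <- simulate_subject(gs, sch, noise_spec("uniform", 1),
                         subject_jitter = 0, seed = 21)
  emp <- crossprod(ts$values) / n
  theo <- t(solve(diag(5) - B)) %*% solve(diag(5) - B)
  se <- sqrt((diag(theo) %o% diag(theo) + theo^2) / n)
  expect_true(all(abs(emp - theo) < 3 * se))
})

test_that("two-node SEM reproduces the closed-form correlation", {
  # A -> B with beta = 0.8, sd(e_B) = 0.6, sd(e_A) = 1  =>  corr = 0.8
  set.seed(31)
  n <- 10000
  eA <- effconn:::draw_noise(noise_spec("uniform", 1), n, 1)
  eB <- effconn:::draw_noise(noise_spec("uniform", 0.6), n, 1)
  A <- eA[, 1]
  B <- 0.8 * A + eB[, 1]
  expect_lt(abs(cor(A, B) - 0.8), 0.02)
})

test_that("zero-coefficient graphs give mutually independent columns", {
  gs <- sample_graph_set(nodes = 6, n_default_edges = 4,
                         n_extra_per_load = c(0, 0, 0),
                         weight_range = c(0, 0), seed = 4)
  sch <- make_schedule(schedule_params(seed = 2))   # ~1000 TRs
  ts <- simulate_subject(gs, sch, seed = 9)
  cors <- cor(ts$values)
  expect_true(max(abs(cors[upper.tri(cors)])) < 0.1)
})

test_that("innovation families show their analytic excess kurtosis", {
  set.seed(12)
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2 - 3
  u <- effconn:::draw_noise(noise_spec("uniform"), 20000, 1)
  l <- effconn:::draw_noise(noise_spec("laplace"), 20000, 1)
  g <- effconn:::draw_noise(noise_spec("gaussian"), 20000, 1)
  expect_lt(abs(kurt(u) - (-1.2)), 0.15)   # uniform: -6/5
  expect_lt(abs(kurt(l) - 3), 0.6)         # laplace: +3
  expect_lt(abs(kurt(g)), 0.2)
  expect_equal(sd(u), 1, tolerance = 0.05)
  expect_equal(sd(l), 1, tolerance = 0.05)
})

test_that("simulation is deterministic under the seed", {
  gs <- sample_graph_set(seed = 2)
  sch <- make_schedule(schedule_params(seed = 1))
  a <- simulate_subject(gs, sch, seed = 5)
  b <- simulate_subject(gs, sch, seed = 5)
  expect_identical(a, b)
  bench1 <- simulate_benchmark(n_vars = 10, n_timepoints = 50, seed = 6)
  bench2 <- simulate_benchmark(n_vars = 10, n_timepoints = 50, seed = 6)
  expect_identical(bench1, bench2)
})

test_that("benchmark returns the requested shapes and an acyclic truth", {
  bench <- simulate_benchmark(n_vars = 20, n_subjects = 4,
                              n_timepoints = 80, edge_density = 0.1,
                              seed = 13)
  expect_length(bench$datasets, 4L)
  for (ds in bench$datasets)
    expect_equal(dim(ds$matrix), c(80L, 20L))
  expect_equal(nrow(bench$graph$edges), round(0.1 * 20 * 19 / 2))
  expect_s3_class(bench$graph, "dag")    # constructor enforces acyclicity
  single <- simulate_benchmark(n_vars = 6, n_subjects = 1,
                               n_timepoints = 40, edge_density = 0.2,
                               seed = 14)
  expect_length(single$datasets, 1L)
  expect_error(simulate_benchmark(n_vars = 5, edge_density = 0.01, seed = 1),
               "fewer than one edge")
})
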