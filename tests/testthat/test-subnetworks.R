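test_that("printed-table parsing honors presence and direction markers", {
  tabs <- load_printed_table(increase_table_path())
  expect_named(tabs, c("prep1", "task1", "prep2", "task2", "prep3",
                       "task3", "rest"), ignore.order = FALSE)
  # RFP->RMFG is present in all 7 conditions, reversed in prep2/prep3/rest
  pres <- vapply(tabs, function(tab) "RFP->RMFG" %in% tab$connection,
                 logical(1))
  expect_true(all(pres))
  rel <- vapply(tabs, function(tab)
    tab$rel_dir[tab$connection == "RFP->RMFG"], integer(1))
  base <- rel[["task1"]]
  expect_equal(unname(rel[c("prep2", "prep3", "rest")]), rep(-base, 3))
  expect_equal(unname(rel[c("prep1", "task2", "task3")]), rep(base, 3))
  # RSFG->ACC appears only at rest
  only_rest <- vapply(tabs, function(tab) "RSFG->ACC" %in% tab$connection,
                      logical(1))
  expect_equal(unname(only_rest),
               c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # the undirected row is carried with dir_known = FALSE
  expect_false(tabs$rest$dir_known[tabs$rest$connection == "LIPS-LSFG"])
  # coefficient cells round-trip: prep1 RFP->RMFG printed as 0.72 (0.3)
  row <- tabs$prep1[tabs$prep1$connection == "RFP->RMFG", ]
  expect_equal(row$mean, 0.72)
  expect_equal(row$sd, 0.3)
})

test_that("malformed fixtures are rejected with the offending row", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("connection\tIntro1\t1-back\tIntro2\t2-back\tIntro3\t3-back\tRest",
               "A->B\t0.5 (0.1)\t\t\t\t\t"), bad)
  expect_error(load_printed_table(bad), "malformed row.*A->B")
  writeLines(c("connection\tIntro1\t1-back\tIntro2\t2-back\tIntro3\t3-back\tRest",
               "A->B\t0.5 (0.1\t\t\t\t\t\t"), bad)
  expect_error(load_printed_table(bad), "cannot parse cell")
})

test_that("the Increase network classifies into 11 default and 1/2/5 prep-related", {
  rep2 <- classify_connections(load_printed_table(increase_table_path()))
  expect_length(rep2$default_edges, 11L)
  expect_equal(lengths(rep2$prep_related), c(`1` = 1L, `2` = 2L, `3` = 5L))
  expect_equal(rep2$prep_related[["1"]], "ACC|RFP")
  expect_setequal(rep2$prep_related[["2"]], c("ACC|Lbas", "RIPS|RSFG"))
  expect_setequal(rep2$prep_related[["3"]],
                  c("ACC|RFP", "ACC|Lbas", "ACC|LSFG", "LIPS|LLOCs",
                    "RIPS|Rprecun"))
  expect_true(all(lengths(rep2$prep_rest_only) == 0L))
})

test_that("the Decrease network classifies into 10 default connections", {
  rep3 <- classify_connections(load_printed_table(decrease_table_path()))
  expect_length(rep3$default_edges, 10L)
  expect_equal(rep3$prep_rest_only[["1"]], "RPlanPol|RTP")
  expect_setequal(rep3$prep_rest_only[["3"]],
                  c("LPCCa|RLOCi", "RPlanPol|RTP"))
  expect_length(rep3$prep_rest_only[["2"]], 0L)
})

test_that("classification set algebra is pure and direction-blind", {
  tabs <- load_printed_table(increase_table_path())
  base <- classify_connections(tabs)
  # permuting row order never changes the report
  shuffled <- lapply(tabs, function(tab) {
    set.seed(40)
    tab[sample(nrow(tab)), ]
  })
  expect_equal(classify_connections(shuffled)[
    c("default_edges", "prep_related", "prep_rest_only")],
    base[c("default_edges", "prep_related", "prep_rest_only")])
  # reversing every direction marker leaves all set sizes unchanged
  flipped <- lapply(tabs, function(tab) { tab$rel_dir <- -tab$rel_dir; tab })
  rep_f <- classify_connections(flipped)
  expect_equal(lengths(rep_f$prep_related), lengths(base$prep_related))
  expect_length(rep_f$default_edges, length(base$default_edges))
  # mutual exclusivity: default vs prep-related, and within each load
  for (k in c("1", "2", "3")) {
    expect_length(intersect(base$default_edges, base$prep_related[[k]]), 0L)
    expect_length(intersect(base$prep_related[[k]],
                            base$prep_rest_only[[k]]), 0L)
  }
})

test_that("empty tables give an empty report and missing conditions error", {
  empty <- lapply(effconn:::condition_labels(), function(cond)
    edge_table(cond, data.frame(node1 = character(0), node2 = character(0),
                                rel_dir = integer(0), mean = numeric(0),
                                sd = numeric(0), dir_known = logical(0))))
  names(empty) <- effconn:::condition_labels()
  rep0 <- classify_connections(empty)
  expect_length(rep0$default_edges, 0L)
  expect_true(all(lengths(rep0$prep_related) == 0L))
  expect_error(classify_connections(empty[-7]), "missing condition.*rest")
})

test_that("reports built from the generating truth score perfect recovery", {
  gs <- sample_graph_set(seed = 50)
  tabs <- lapply(effconn:::condition_labels(), function(cond) {
    e <- condition_graph(gs, cond)$edges
    edge_table(cond, data.frame(
      node1 = pmin(e[, 1], e[, 2]), node2 = pmax(e[, 1], e[, 2]),
      rel_dir = ifelse(e[, 1] < e[, 2], 1L, -1L),
      mean = 0.5, sd = 0.1, dir_known = TRUE))
  })
  names(tabs) <- effconn:::condition_labels()
  report <- classify_connections(tabs)
  acc <- compare_to_truth(report, gs)
  expect_true(all(acc$precision == 1))
  expect_true(all(acc$recall == 1))
  # truth with no extras: prep-related recall reported as not applicable
  gs0 <- sample_graph_set(n_extra_per_load = c(0, 0, 0), seed = 51)
  tabs0 <- lapply(effconn:::condition_labels(), function(cond) {
    e <- condition_graph(gs0, cond)$edges
    edge_table(cond, data.frame(
      node1 = pmin(e[, 1], e[, 2]), node2 = pmax(e[, 1], e[, 2]),
      rel_dir = 1L, mean = 0.5, sd = 0.1, dir_known = TRUE))
  })
  names(tabs0) <- effconn:::condition_labels()
  acc0 <- compare_to_truth(classify_connections(tabs0), gs0)
  expect_true(all(is.na(acc0$recall[acc0$class != "default"])))
  # a report over disjoint labels errors; disjoint edges score precision 0
  fake <- classify_connections(tabs)
  fake$default_edges <- c("ROI01|ROI17")
  fake$prep_related <- list(`1` = character(0), `2` = character(0),
                            `3` = character(0))
  fake$prep_rest_only <- fake$prep_related
  acc_f <- compare_to_truth(fake, gs)
  if (!("ROI01|ROI17" %in% pair_keys_of(skeleton_of(condition_graph(gs, "rest")))))
    expect_equal(acc_f$precision[acc_f$class == "default"], 0)
})
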