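test_that("epoch composition sums to one and counts exclusive clusters", {
  recs <- rbind(mock_records(c("c1", "c2"), epoch = "cultured"),
                mock_records(c("n1", "n2", "n3")))
  part <- data.frame(id = c("c1", "c2", "n1", "n2", "n3"),
                     cluster = c("X", "X", "X", "X", "Y"), kind = "LC",
                     threshold = 85)
  comp <- epoch_composition(part, recs)
  x <- comp[comp$cluster == "X", ]
  expect_equal(x$frac_cultured + x$frac_prior_env + x$frac_new_survey, 1)
  expect_equal(x$frac_cultured, 0.5)
  expect_equal(comp$frac_new_survey[comp$cluster == "Y"], 1)
})

test_that("the novelty rule requires exclusivity and a sub-cutoff mean identity", {
  cult <- mock_records("ref1", epoch = "cultured")
  recs <- rbind(mock_records(c("m1", "m2", "m3")), cult,
                mock_records("m4"))
  lc <- data.frame(id = c("m1", "m2", "m3", "ref1", "m4"),
                   cluster = c("L1", "L1", "L1", "L2", "L2"),
                   kind = "LC", threshold = 85)
  best96 <- mock_hits(c("m1", "m2", "m3"), "ref1", c(96, 96, 96))
  best94 <- mock_hits(c("m1", "m2", "m3"), "ref1", c(94, 94, 94))

  # mean 96 >= 95: not novel; L2 contains a cultured node: never novel
  expect_identical(nrow(novel_lcs(lc, recs, cult, hits = best96)), 0L)
  nv <- novel_lcs(lc, recs, cult, hits = best94)
  expect_identical(nv$cluster, "L1")
  expect_equal(nv$mean_identity, 94)

  # members with no qualifying hit count as identity 0
  nv2 <- novel_lcs(lc, recs, cult, hits = mock_hits("m1", "ref1", 96))
  expect_identical(nv2$cluster, "L1")
  expect_equal(nv2$mean_identity, 32)

  expect_error(novel_lcs(lc, recs, recs[0, ], hits = best94), "cultured")
})

test_that("distance to culture is BFS edge count, infinite when unreachable", {
  recs <- rbind(mock_records("cul", epoch = "cultured"),
                mock_records(c("e1", "e2", "x1", "x2")))
  hits <- mock_hits(c("cul", "e1", "x1"), c("e1", "e2", "x2"), c(97, 97, 97))
  net <- build_network(hits, recs, 97)
  d <- distance_to_culture(net)
  expect_identical(unname(d[c("e1", "e2")]), c(1, 2))
  expect_identical(unname(d["x1"]), Inf)
  expect_false("cul" %in% names(d))

  # distance classes partition the environmental nodes
  frac1 <- mean(d == 1); frac_gt <- mean(is.finite(d) & d > 1)
  frac_inf <- mean(is.infinite(d))
  expect_equal(frac1 + frac_gt + frac_inf, 1)
})

test_that("distance to culture agrees with an all-pairs BFS oracle on random graphs", {
  set.seed(91)
  for (k in 1:20) {
    n <- sample(8:50, 1)
    g <- igraph::sample_gnp(n, 0.08)
    deg <- igraph::degree(g)
    if (!any(deg > 0)) next
    g <- igraph::induced_subgraph(g, which(deg > 0))
    nn <- igraph::vcount(g)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(nn))
    epoch <- sample(c("cultured", "new_survey"), nn, replace = TRUE,
                    prob = c(0.2, 0.8))
    igraph::V(g)$epoch <- epoch
    d <- distance_to_culture(g)
    full <- igraph::distances(g, weights = NA)  # oracle: all-pairs BFS
    cult <- which(epoch == "cultured")
    for (id in names(d)) {
      i <- match(id, igraph::V(g)$name)
      want <- if (length(cult) == 0) Inf else min(full[i, cult])
      expect_identical(unname(d[id]), want)
    }
  }
})

test_that("closeness is per component with hand-checked path and clique values", {
  recs <- mock_records(c("A", "B", "C", "D", "E", "F", "G"))
  hits <- rbind(mock_hits(c("A", "B"), c("B", "C"), c(97, 97)),   # path A-B-C
                mock_hits(c("D", "D", "E"), c("E", "F", "F"), c(97, 97, 97)),
                mock_hits("G", "A", 50))  # below threshold: G excluded
  net <- build_network(hits, recs, 97)
  cl <- node_closeness(net)
  expect_equal(unname(cl["B"]), 1)
  expect_equal(unname(cl["A"]), 2 / 3)
  expect_equal(unname(cl[c("D", "E", "F")]), rep(1, 3))  # triangle = clique
  expect_false("G" %in% names(cl))
  # chain ends are strictly less central than the centre
  expect_lt(cl["C"], cl["B"])
})

test_that("one-sided closeness contrasts detect separation and ignore identical groups", {
  same <- closeness_contrast(rep(c(0.4, 0.6), 20), rep(c(0.4, 0.6), 20))
  expect_gt(same$p_value, 0.9)
  expect_false(same$significant_05)

  sep <- closeness_contrast(rep(1, 30), rep(0.2, 30))
  expect_lt(sep$p_value, 0.01)
  expect_true(sep$significant_01)

  # wrong direction: environmental higher than cultured is not significant
  wrong <- closeness_contrast(rep(0.2, 30), rep(1, 30))
  expect_gt(wrong$p_value, 0.5)
  expect_error(closeness_contrast(numeric(0), 1), "non-empty")
})

test_that("cultured references are more central than survey sequences in the planted scenario", {
  run <- scenario_run("endemic")
  epoch <- stats::setNames(run$sim$records$epoch, run$sim$records$id)
  cl99 <- node_closeness(run$nets$t99)
  cult <- cl99[epoch[names(cl99)] == "cultured"]
  env <- cl99[epoch[names(cl99)] == "new_survey"]
  expect_gt(mean(cult, na.rm = TRUE), mean(env, na.rm = TRUE))
  ct <- closeness_contrast(cult[!is.na(cult)], env[!is.na(env)])
  expect_true(ct$significant_01)

  # prior-environmental sequences sit between cultured anchors and the survey
  pre <- cl99[epoch[names(cl99)] == "prior_env"]
  ct2 <- closeness_contrast(cult[!is.na(cult)], pre[!is.na(pre)])
  expect_lt(ct2$p_value, 0.05)
})

test_that("the novelty report assembles consistent tables", {
  run <- scenario_run("endemic")
  rep <- novelty_report(run$nets$t85, run$cc85, run$lc85, run$sim$records,
                        run$cultured, run$hits)
  expect_true(all(abs(rep$composition$frac_cultured +
                        rep$composition$frac_prior_env +
                        rep$composition$frac_new_survey - 1) < 1e-12))
  expect_true(all(rep$novel$cluster %in%
                    rep$exclusive$cluster[rep$exclusive$epoch == "new_survey"]))
  expect_true(all(is.na(rep$node_measures$distance_to_culture) |
                    rep$node_measures$distance_to_culture >= 1))
  expect_named(rep$contrasts, c("cultured_vs_prior", "cultured_vs_all_env"))
})
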