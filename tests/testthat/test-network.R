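test_that("build_network applies the threshold, drops singletons and validates input", {
  fm <- figure_mock()
  expect_error(build_network(fm$hits, fm$records, 0), "threshold")
  expect_error(build_network(fm$hits, fm$records, 101), "threshold")
  net100 <- build_network(fm$hits, fm$records, 100)
  expect_equal(igraph::vcount(net100), 0)
  net97 <- build_network(fm$hits, fm$records, 97)
  expect_equal(igraph::vcount(net97), 5)  # all nodes still have an edge
  net98 <- build_network(fm$hits, fm$records, 98)
  expect_setequal(igraph::V(net98)$name, c("A", "B"))  # others singleton
  # labels travel onto vertices
  expect_identical(sort(unique(igraph::V(net97)$epoch)), "new_survey")
})

test_that("modularity matches closed forms and the igraph reference", {
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- letters[1:4]
  igraph::E(ring)$weight <- 1
  one <- stats::setNames(rep("c1", 4), letters[1:4])
  singles <- stats::setNames(letters[1:4], letters[1:4])
  expect_equal(graph_modularity(ring, one), 0, tolerance = 1e-12)
  expect_equal(graph_modularity(ring, singles), -0.25, tolerance = 1e-12)

  set.seed(61)
  for (k in 1:20) {
    g <- random_weighted_graph(sample(6:25, 1), 0.3, seed = 600 + k)
    if (igraph::ecount(g) == 0) next
    memb <- sample(1:3, igraph::vcount(g), replace = TRUE)
    names(memb) <- igraph::V(g)$name
    expect_equal(graph_modularity(g, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
    expect_equal(graph_modularity(g, memb, weighted = FALSE),
                 igraph::modularity(g, memb), tolerance = 1e-12)
  }
})

test_that("level-1 Louvain is deterministic per seed, beats singletons, and refines components", {
  set.seed(71)
  for (k in 1:15) {
    g <- random_weighted_graph(sample(8:30, 1), 0.15, seed = 700 + k)
    deg <- igraph::degree(g)
    if (!any(deg > 0)) next
    g <- igraph::induced_subgraph(g, which(deg > 0))
    lc1 <- louvain_level1(g, seed = 42)
    lc2 <- louvain_level1(g, seed = 42)
    expect_identical(lc1, lc2)
    singles <- stats::setNames(igraph::V(g)$name, igraph::V(g)$name)
    expect_gte(graph_modularity(g, lc1),
               graph_modularity(g, singles) - 1e-12)
    # refinement: every LC lies inside one CC
    cc <- connected_components(g)
    cc_of <- stats::setNames(cc$cluster, cc$id)
    per_lc <- tapply(cc_of[lc1$id], lc1$cluster,
                     function(x) length(unique(x)))
    expect_true(all(per_lc == 1))
  }

  # a single clique stays one community
  kq <- igraph::make_full_graph(5)
  igraph::V(kq)$name <- letters[1:5]
  igraph::E(kq)$weight <- 1
  expect_length(unique(louvain_level1(kq, seed = 1)$cluster), 1L)
})

test_that("raising the threshold only ever splits components, never merges them", {
  run <- scenario_run("endemic")
  taus <- c(85, 90, 95, 96, 97, 98, 99)
  parts <- lapply(taus, function(tau)
    connected_components(run$nets[[sprintf("t%d", tau)]]))
  for (i in seq_len(length(taus) - 1)) {
    lo <- parts[[i]]; hi <- parts[[i + 1]]
    common <- intersect(lo$id, hi$id)
    lo_of <- stats::setNames(lo$cluster, lo$id)
    per_hi <- tapply(lo_of[common],
                     stats::setNames(hi$cluster, hi$id)[common],
                     function(x) length(unique(x)))
    expect_true(all(per_hi == 1))
  }
})

test_that("the giant component and deterministic tie-breaks behave as documented", {
  fm <- figure_mock()
  net <- build_network(fm$hits, fm$records, 97)
  gc <- giant_component(net)
  cc <- connected_components(net)
  expect_identical(sort(cc$id[cc$cluster == gc]), c("A", "B", "C"))

  # tie 2 vs 2: lexicographically smallest cluster id wins
  recs <- mock_records(c("a", "b", "x", "y"))
  hits <- mock_hits(c("a", "x"), c("b", "y"), c(97, 97))
  net2 <- build_network(hits, recs, 97)
  expect_identical(giant_component(net2), "CC_a")
})

test_that("the supernode quotient graph contracts communities and carries composition", {
  recs <- rbind(mock_records(c("a", "b", "c"), site = "site_1"),
                mock_records(c("d", "e"), site = "site_2"))
  recs$epoch[recs$id %in% c("d", "e")] <- "prior_env"
  recs$site[recs$id %in% c("d", "e")] <- NA
  recs$habitat[recs$id %in% c("d", "e")] <- NA
  hits <- mock_hits(c("a", "b", "d", "c"), c("b", "c", "e", "d"),
                    c(99, 99, 99, 97))
  net <- build_network(hits, recs, 97)
  lc <- new_lc <- data.frame(id = c("a", "b", "c", "d", "e"),
                             cluster = c("L1", "L1", "L1", "L2", "L2"),
                             kind = "LC", threshold = 97)
  sg <- supernode_graph(net, lc)
  expect_equal(igraph::vcount(sg$graph), 2)
  expect_equal(igraph::ecount(sg$graph), 1)
  expect_setequal(igraph::V(sg$graph)$size, c(3L, 2L))
  comp <- sg$composition
  frac_new <- comp$fraction[comp$supernode == "L1" & comp$class == "epoch" &
                              comp$value == "new_survey"]
  expect_equal(frac_new, 1)

  # no crossing edges -> edgeless quotient
  hits2 <- mock_hits(c("a", "b", "d"), c("b", "c", "e"), c(99, 99, 99))
  net2 <- build_network(hits2, recs, 97)
  sg2 <- supernode_graph(net2, lc)
  expect_equal(igraph::ecount(sg2$graph), 0)
})

test_that("graph and partition exports are stable and re-readable", {
  fm <- figure_mock()
  net <- build_network(fm$hits, fm$records, 96)
  f_el <- tempfile(fileext = ".tsv"); f_gml <- tempfile(fileext = ".graphml")
  f_pt <- tempfile(fileext = ".tsv")
  write_edge_list(net, f_el)
  el <- utils::read.delim(f_el)
  expect_identical(nrow(el), 4L)
  expect_true(all(c("node1", "node2", "pct_identity") %in% names(el)))
  write_graphml(net, f_gml)
  g2 <- igraph::read_graph(f_gml, format = "graphml")
  expect_identical(igraph::vcount(g2), igraph::vcount(net))
  expect_identical(igraph::ecount(g2), igraph::ecount(net))
  write_partition(connected_components(net), f_pt)
  pt <- utils::read.delim(f_pt)
  expect_identical(sort(names(pt)), sort(c("id", "cluster", "kind", "threshold")))
  unlink(c(f_el, f_gml, f_pt))
})
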