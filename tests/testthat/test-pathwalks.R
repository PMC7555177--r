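small_cfg <- function(seed = 1, n_steps = 1500, n_walkers = 2) {
  walk_config(n_walkers = n_walkers, n_steps = n_steps, seed = seed)
}

named_graph <- function(edges) {
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE)
}

test_that("walks are deterministic under seed and conserve visit totals", {
  fx <- walk_fixture()
  gm <- guide_scores(fx$collection[[3]], fx$collection)
  a <- guided_walk(fx$network, gm, small_cfg(seed = 9))
  b <- guided_walk(fx$network, gm, small_cfg(seed = 9))
  expect_identical(a$visits, b$visits)
  expect_identical(a$edge_traversals, b$edge_traversals)
  expect_identical(a$total, sum(a$visits))
  t1 <- topology_walk(fx$network, small_cfg(seed = 4))
  expect_identical(t1$total, sum(t1$visits))
})

test_that("guide mass on one node of a path graph makes it the most
           visited", {
  path <- named_graph(cbind(paste0("n", 1:5), paste0("n", 2:6)))
  mass <- stats::setNames(c(0, 0, 1, 0, 0, 0), paste0("n", 1:6))
  wc <- guided_walk(path, mass, small_cfg(seed = 21))
  expect_equal(names(which.max(wc$visits)), "n3")
})

test_that("uniform guidance is the guidance-free limit", {
  fx <- walk_fixture()
  mass <- stats::setNames(rep(1, igraph::vcount(fx$network)),
                          igraph::V(fx$network)$name)
  # identical mechanics: a uniformly guided walk IS the topology walk
  g <- guided_walk(fx$network, mass, walk_config(3, 5000, seed = 101))
  t <- topology_walk(fx$network, walk_config(3, 5000, seed = 101))
  expect_identical(g$visits, t$visits)
  # and across independent seeds the visit distributions stay close
  t2 <- topology_walk(fx$network, walk_config(3, 5000, seed = 202))
  expect_lt(max(abs(g$visits / g$total - t2$visits / t2$total)), 0.02)
})

test_that("topology walk degenerate graphs behave combinatorially", {
  # single node: the whole budget is recorded on that node
  single <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices("only")
  wc <- topology_walk(single, walk_config(2, 100, seed = 1))
  expect_equal(unname(wc$visits["only"]), wc$total)
  expect_gte(wc$total, 200)
  # star: the hub lies on every inter-leaf shortest path
  star <- named_graph(cbind("hub", paste0("leaf", 1:6)))
  ws <- topology_walk(star, small_cfg(seed = 31))
  expect_equal(names(which.max(ws$visits)), "hub")
  # complete graph: frequencies equal within sampling error
  kn <- igraph::make_full_graph(8)
  igraph::V(kn)$name <- paste0("v", 1:8)
  wk <- topology_walk(kn, walk_config(4, 4000, seed = 7))
  expect_lt(max(abs(wk$visits / wk$total - 1 / 8)), 0.02)
})

test_that("walkers never leave the largest component and guidance must
           reach it", {
  two_comp <- named_graph(rbind(c("a1", "a2"), c("a2", "a3"),
                                c("b1", "b2")))
  wc <- topology_walk(two_comp, small_cfg(seed = 2))
  expect_setequal(names(wc$visits), c("a1", "a2", "a3"))
  expect_setequal(wc$dropped_nodes, c("b1", "b2"))
  mass <- c(a1 = 0, a2 = 0, a3 = 0, b1 = 1, b2 = 1)
  expect_error(guided_walk(two_comp, mass, small_cfg()),
               "guidance error")
})

test_that("odds ratio reproduces the defining formula", {
  # worked example: F_iG = 30 of 100, F_iT = 10 of 100
  g <- make_walk_counts(c(p1 = 30, p2 = 70))
  t <- make_walk_counts(c(p1 = 10, p2 = 90))
  ort <- odds_ratio(g, t)
  expect_equal(ort$OR[ort$pathway_id == "p1"], 27 / 7, tolerance = 1e-12)
  # identical counts: OR exactly 1 everywhere
  same <- odds_ratio(g, g)
  expect_true(all(same$OR == 1))
  # node unvisited by the topology run is flagged, not scored
  g2 <- make_walk_counts(c(p1 = 5, p2 = 5, p3 = 10))
  t2 <- make_walk_counts(c(p1 = 0, p2 = 10, p3 = 10))
  ort2 <- odds_ratio(g2, t2)
  expect_true(ort2$unscorable[ort2$pathway_id == "p1"])
  expect_true(is.na(ort2$OR[ort2$pathway_id == "p1"]))
  expect_error(odds_ratio(g, make_walk_counts(c(q1 = 1, q2 = 1))),
               "different node sets")
})

test_that("odds ratios match brute-force re-evaluation on random counts", {
  withr::with_seed(77, {
    for (i in 1:50) {
      n <- sample(3:30, 1)
      fg <- stats::rpois(n, 40) + 1
      ft <- stats::rpois(n, 40) + 1
      names(fg) <- names(ft) <- sprintf("p%02d", seq_len(n))
      ort <- odds_ratio(make_walk_counts(fg), make_walk_counts(ft))
      expect_equal(ort$OR, unname(oracle_odds_ratio(fg, ft))[
        match(ort$pathway_id, names(fg))], tolerance = 1e-14)
    }
  })
})

test_that("clustering splits cliques joined by a bridge and is seeded", {
  clique <- function(nodes) t(utils::combn(nodes, 2))
  g <- named_graph(rbind(clique(paste0("a", 1:4)),
                         clique(paste0("b", 1:4)),
                         c("a1", "b1")))
  gm <- stats::setNames(rep(1, 8), igraph::V(g)$name)
  wc <- guided_walk(g, gm, small_cfg(seed = 3, n_steps = 3000))
  part <- cluster_pathways(g, wc, seed = 5)
  expect_equal(length(unique(part$cluster)), 2)
  cl <- stats::setNames(part$cluster, part$pathway_id)
  expect_length(unique(cl[paste0("a", 1:4)]), 1)
  expect_length(unique(cl[paste0("b", 1:4)]), 1)
  # the weighted modularity of the recovered bipartition is maximal over
  # all bipartitions (exhaustive oracle on 8 nodes)
  el <- igraph::as_edgelist(g)
  w <- wc$edge_traversals[cbind(el[, 1], el[, 2])] + 1
  best <- -Inf
  for (mask in 0:(2^8 - 1)) {
    memb <- as.integer(intToBits(mask))[1:8] + 1L
    best <- max(best, igraph::modularity(g, memb, weights = w))
  }
  expect_equal(attr(part, "modularity"), best, tolerance = 1e-9)
  # single clique stays one cluster; same seed twice is identical
  g1 <- named_graph(clique(paste0("c", 1:5)))
  gm1 <- stats::setNames(rep(1, 5), paste0("c", 1:5))
  wc1 <- guided_walk(g1, gm1, small_cfg(seed = 8))
  expect_equal(length(unique(cluster_pathways(g1, wc1)$cluster)), 1)
  expect_identical(cluster_pathways(g, wc, seed = 5),
                   cluster_pathways(g, wc, seed = 5))
})

test_that("guide scores count guide genes per pathway", {
  coll <- gene_set_collection(list(P = c("x", "y", "z"), Q = c("z", "w")))
  gs <- guide_scores(c("x", "z"), coll)
  expect_equal(unname(gs), c(2, 1))
  expect_error(guide_scores("absent", coll), "guidance error")
})
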