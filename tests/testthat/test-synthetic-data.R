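test_that("cohort generation is deterministic and respects the null", {
  spec <- cohort_spec(n_datasets = 2, n_genes = 100, n_affected = 4,
                      n_control = 4, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$datasets[[1]]$values, b$datasets[[1]]$values)
  expect_identical(a$datasets[[2]]$values, b$datasets[[2]]$values)
  # no perturbation configured -> empty ground truth
  expect_true(all(vapply(a$truth$perturbed, nrow, integer(1)) == 0))
})

test_that("invalid cohort specs fail naming the offending field", {
  expect_error(cohort_spec(n_affected = 1), "n_affected")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(consistent_fraction = 0), "consistent_fraction")
  expect_error(cohort_spec(dialect = "counts"), "dialect")
  expect_error(
    cohort_spec(perturbed_sets = list(s = list(genes = "nope",
                                               effect = 1))),
    "perturbed_sets")
})

test_that("planted effects are recoverable by a reference t-test", {
  genes <- gene_universe(1000)
  spec <- cohort_spec(n_datasets = 1, n_genes = 1000, n_affected = 10,
                      n_control = 10, noise_sd = 0.5,
                      perturbed_sets = list(
                        s1 = list(genes = genes[1:50], effect = 1.0)),
                      seed = 17)
  ch <- generate_cohort(spec)
  ds <- ch$datasets[[1]]
  p <- oracle_t_test(ds$values, ds$groups)
  # power of a 10v10 t-test at delta = 1, sd = 0.5 is essentially 1;
  # the >= 80% recovery bound leaves room for sampling noise
  expect_gte(mean(p[genes[1:50]] < 0.05), 0.8)
  expect_setequal(ch$truth$perturbed[[1]]$gene, genes[1:50])
})

test_that("null cohort gene-wise p-values are uniform", {
  spec <- cohort_spec(n_datasets = 1, n_genes = 5000, n_affected = 5,
                      n_control = 5, seed = 23)
  ds <- generate_cohort(spec)$datasets[[1]]
  p <- oracle_t_test(ds$values, ds$groups)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("consistent_fraction activates perturbations in the right number
           of datasets", {
  genes <- gene_universe(200)
  spec <- cohort_spec(n_datasets = 6, n_genes = 200, n_affected = 3,
                      n_control = 3, consistent_fraction = 1 / 3,
                      perturbed_sets = list(
                        s1 = list(genes = genes[1:10], effect = 2)),
                      seed = 2)
  ch <- generate_cohort(spec)
  expect_length(ch$truth$active_datasets$s1, ceiling(6 / 3))
  active <- which(vapply(ch$truth$perturbed, nrow, integer(1)) > 0)
  expect_identical(active, as.integer(ch$truth$active_datasets$s1))
})

test_that("dialects produce linear and negative-valued exports", {
  spec_lin <- cohort_spec(n_datasets = 1, n_genes = 50, n_affected = 3,
                          n_control = 3, dialect = "linear", seed = 3)
  lin <- generate_cohort(spec_lin)$datasets[[1]]
  expect_false(lin$is_log2)
  expect_true(all(lin$values > 0))
  spec_neg <- cohort_spec(n_datasets = 1, n_genes = 50, n_affected = 3,
                          n_control = 3,
                          dialect = "linear_with_negatives", seed = 3)
  neg <- generate_cohort(spec_neg)$datasets[[1]]
  expect_lt(min(neg$values), 0)
})

test_that("duplicate probes with flipped signs exercise the multi-sign
           filter", {
  genes <- gene_universe(100)
  spec <- cohort_spec(n_datasets = 1, n_genes = 100, n_affected = 8,
                      n_control = 8, duplicate_probes = TRUE,
                      flip_fraction = 0.5, noise_sd = 0.3,
                      perturbed_sets = list(
                        s1 = list(genes = genes[1:10], effect = 2)),
                      seed = 4)
  ch <- generate_cohort(spec)
  ds <- ch$datasets[[1]]
  expect_equal(nrow(ds$values), 200)
  expect_length(ch$truth$flipped_genes$s1, 5)
  expect_named(ch$truth$gene_map)
  deg <- diff_expression(ds, gene_map = ch$truth$gene_map)
  filtered <- filter_degs(deg)
  # flipped genes carry probes of opposite sign and must be removed
  expect_length(intersect(filtered$gene, ch$truth$flipped_genes$s1), 0)
  # unflipped perturbed genes survive as a single row each
  surviving <- setdiff(genes[1:10], ch$truth$flipped_genes$s1)
  expect_true(all(surviving %in% filtered$gene))
  expect_false(any(duplicated(filtered$gene)))
})

test_that("pathway generation honors size, overlap and disjointness", {
  uni <- gene_universe(500)
  disjoint <- generate_pathways(10, c(5, 10), uni, overlap_fraction = 0,
                                seed = 1)
  sizes <- lengths(disjoint)
  expect_true(all(sizes >= 5 & sizes <= 10))
  all_genes <- unlist(disjoint)
  expect_false(any(duplicated(all_genes)))

  ov <- generate_pathways(2, c(5, 5), uni, overlap_fraction = 0.4,
                          seed = 2)
  a <- ov[[1]]; b <- ov[[2]]
  jac <- length(intersect(a, b)) / length(union(a, b))
  expect_gte(jac, 0.4)

  expect_error(generate_pathways(2, c(5, 5), character(0)), "empty")
  expect_error(generate_pathways(2, c(3, 3), gene_universe(100),
                                 overlap_fraction = 1),
               "configuration error")
  expect_error(generate_pathways(5, c(30, 30), gene_universe(100),
                                 overlap_fraction = 0),
               "configuration error")
})

test_that("pathway network edges follow the shared-gene rule", {
  coll <- gene_set_collection(list(A = c("g1", "g2", "g3", "g4"),
                                   B = c("g3", "g4", "g5", "g6"),
                                   C = c("x1", "x2", "x3")))
  net3 <- generate_pathway_network(coll, min_shared = 2)
  expect_true(igraph::are_adjacent(net3, "A", "B"))
  # C shares nothing: only reachable through the backbone
  expect_true(igraph::graph_attr(net3, "backbone_added"))
  expect_equal(igraph::components(net3)$no, 1)

  # min_shared = 0 -> complete graph
  net0 <- generate_pathway_network(coll, min_shared = 0)
  expect_equal(igraph::ecount(net0), choose(3, 2))

  # disjoint sets, min_shared = 1 -> no native (non-backbone) edge
  coll2 <- gene_set_collection(list(A = c("g1", "g2"), B = c("g3", "g4")))
  net1 <- generate_pathway_network(coll2, min_shared = 1)
  expect_true(all(igraph::E(net1)$backbone))
})

test_that("synthetic PPI tables respect module structure", {
  # single 3-gene module at density 1 -> the 3 edges of K3
  tab <- generate_ppi_table(c("a", "b", "c"),
                            c(a = "m1", b = "m1", c = "m1"),
                            intra_density = 1, seed = 1)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$combined_score >= 0.75))

  expect_equal(nrow(generate_ppi_table(character(0), character(0))), 0)

  # inter-module scores below 0.5 never survive a 0.700 threshold
  genes <- c(paste0("a", 1:5), paste0("b", 1:5))
  mods <- stats::setNames(rep(c("m1", "m2"), each = 5), genes)
  tab2 <- generate_ppi_table(genes, mods, inter_score_range = c(0, 0.5),
                             inter_density = 1, seed = 2)
  g <- ppi_graph(tab2, threshold = 0.700)
  el <- igraph::as_edgelist(g)
  expect_true(all(mods[el[, 1]] == mods[el[, 2]]))

  expect_error(generate_ppi_table(genes, mods,
                                  intra_score_range = c(0.5, 1.2)),
               "configuration error")
})
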