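# Small fixture builders shared across test files.

make_dataset <- function(m, groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (is.null(groups)) {
    half <- ncol(m) %/% 2
    groups <- stats::setNames(
      rep(c("affected", "control"), c(half, ncol(m) - half)), colnames(m))
  }
  expression_dataset(m, groups)
}

make_deg_table <- function(gene, log2FC, p_value,
                           probe = sprintf("p%d", seq_along(gene))) {
  out <- data.frame(probe = probe, gene = gene, log2FC = log2FC,
                    p_value = p_value,
                    adj_p = stats::p.adjust(p_value, "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

# the hand-built 12-row DEG table exercising every filtering rule:
# a multi-sign gene, a same-sign duplicate, LOC/FLJ/RP prefixes, a
# fold-change boundary gene, and a p-value failure
cascade_fixture <- function() {
  make_deg_table(
    gene = c("GENEA", "GENEA", "GENEB", "GENEB", "LOC100128", "GENEC",
             "GENED", "GENEE", "FLJ12345", "RPL13A", "GENEF", "GENEG"),
    log2FC = c(1.2, -0.8, 1.2, 0.5, 2.0, 0.585, -0.9, 0.3, -1.1, 0.7,
               0.6, -0.5),
    p_value = c(0.01, 0.03, 0.01, 0.04, 0.001, 0.001, 0.02, 0.2, 0.01,
                0.01, 0.049, 0.01))
}

# two 4-cliques joined by a single bridge edge, with scores
two_clique_ppi <- function() {
  clique_edges <- function(nodes) {
    t(utils::combn(nodes, 2))
  }
  e <- rbind(clique_edges(c("a1", "a2", "a3", "a4")),
             clique_edges(c("b1", "b2", "b3", "b4")),
             c("a1", "b1"))
  data.frame(protein1 = e[, 1], protein2 = e[, 2],
             combined_score = 0.9, stringsAsFactors = FALSE)
}

# deterministic small pathway network fixture used by several walk tests
walk_fixture <- function(n_pathways = 30, n_genes = 400, seed = 11) {
  coll <- generate_pathways(n_pathways, c(8, 25), gene_universe(n_genes),
                            overlap_fraction = 0.2, seed = seed)
  net <- generate_pathway_network(coll, min_shared = 1, seed = seed)
  list(collection = coll, network = net)
}

# builds a complete small study on disk: three datasets in mixed export
# dialects, a pathway collection with two designated target pathways
# holding the planted genes, a shared-membership network, and a PPI table
build_study <- function(dir, seed = 1, effect = 1.5) {
  genes <- gene_universe(400)
  sig <- genes[1:30]
  met <- genes[21:45]
  spec <- cohort_spec(
    n_datasets = 3, n_genes = 400, n_affected = 8, n_control = 8,
    noise_sd = 0.5,
    perturbed_sets = list(sig = list(genes = sig, effect = effect)),
    seed = seed)
  ch <- generate_cohort(spec)
  dialects <- c("log2", "linear", "linear_with_negatives")
  entries <- list()
  for (i in 1:3) {
    ds <- ch$datasets[[i]]
    if (dialects[i] != "log2") {
      m <- 2^ds$values
      if (dialects[i] == "linear_with_negatives") m <- m - (min(m) + 1)
      ds <- expression_dataset(m, ds$groups, is_log2 = FALSE,
                               dataset_id = ds$dataset_id)
    }
    path <- file.path(dir, sprintf("ds%d.txt", i))
    write_series_matrix(ds, path)
    gm_path <- file.path(dir, sprintf("ds%d_groups.tsv", i))
    write_group_map(ds$groups, gm_path)
    entries[[i]] <- list(path = path, group_map = gm_path,
                         tissue = "fibroblast", phenotype = "ataxia",
                         is_log2 = ds$is_log2)
  }
  coll <- generate_pathways(25, c(10, 25), genes, overlap_fraction = 0.15,
                            seed = seed + 1)
  sets <- c(as.list(coll), list(sig = sig, met = met))
  coll2 <- gene_set_collection(sets, universe = genes)
  gmt <- file.path(dir, "sets.gmt")
  write_gmt(coll2, gmt)
  net <- generate_pathway_network(coll2, min_shared = 2, seed = seed + 2)
  el_path <- file.path(dir, "network.tsv")
  el <- igraph::as_edgelist(net)
  write_edge_list(data.frame(from = el[, 1], to = el[, 2]), el_path)
  ppi_genes <- union(sig, met)
  mods <- stats::setNames(rep(c("m1", "m2"),
                              length.out = length(ppi_genes)),
                          ppi_genes)
  ppi <- generate_ppi_table(ppi_genes, mods, seed = seed + 3)
  ppi_path <- file.path(dir, "ppi.tsv")
  write_ppi_table(ppi, ppi_path)
  pipeline_config(entries, gene_sets = gmt, pathway_network = el_path,
                  ppi = ppi_path, target_pathways = c("sig", "met"),
                  seed = seed)
}
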