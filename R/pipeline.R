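# Config-driven orchestration of the full analysis chain: per-dataset
# harmonization and differential expression, per-tissue enrichment and
# consistency aggregation, guided/topology walks with odds ratios and
# clustering, and PPI module detection — with seeded determinism and a
# manifest recording every threshold.

#' Pipeline configuration
#'
#' @param datasets list of dataset entries; each a list with `path`
#'   (series matrix file), `group_map` (named vector or TSV path),
#'   `tissue`, `phenotype` (`"ataxia"`/`"spasticity"`), optional `is_log2`
#'   (NA = auto-detect) and optional `gene_map` (named probe -> gene
#'   vector).
#' @param gene_sets a [gene_set_collection()] or path to a GMT file.
#' @param pathway_network an `igraph` or path to a 2-column edge list.
#' @param ppi a PPI data.frame (protein1, protein2, combined_score) or
#'   path to the 3-column TSV; optional (`NULL` skips the PPI stage).
#' @param target_pathways character vector of pathway IDs whose member
#'   genes guide the walks (e.g. the signaling and metabolism pathways of
#'   interest); first entry is treated as the signaling set and second as
#'   the metabolism set for PPI annotation.
#' @param p_thresh,lfc_thresh,top_n,min_fraction,ppi_threshold numeric
#'   thresholds (defaults 0.05, 0.585, 500, 1/3, 0.700).
#' @param n_walkers,n_steps,restart_every walk parameters (defaults 6,
#'   10000, 50).
#' @param seed master integer seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets, gene_sets, pathway_network,
                            ppi = NULL, target_pathways = character(0),
                            p_thresh = 0.05, lfc_thresh = 0.585,
                            top_n = 500, min_fraction = 1/3,
                            ppi_threshold = 0.700, n_walkers = 6,
                            n_steps = 10000, restart_every = 50,
                            seed = 1) {
  if (length(datasets) == 0) {
    stop("pipeline validation error: no datasets configured",
         call. = FALSE)
  }
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (is.null(d$tissue) || is.null(d$phenotype)) {
      stop("pipeline validation error: dataset ", i,
           " lacks tissue/phenotype", call. = FALSE)
    }
    if (is.null(d$data) && (is.null(d$path) || !file.exists(d$path))) {
      stop("pipeline validation error: dataset ", i,
           " path missing or nonexistent", call. = FALSE)
    }
  }
  stopifnot(p_thresh > 0, lfc_thresh >= 0, top_n > 0,
            min_fraction > 0, ppi_threshold > 0)
  structure(list(datasets = datasets, gene_sets = gene_sets,
                 pathway_network = pathway_network, ppi = ppi,
                 target_pathways = target_pathways, p_thresh = p_thresh,
                 lfc_thresh = lfc_thresh, top_n = top_n,
                 min_fraction = min_fraction,
                 ppi_threshold = ppi_threshold, n_walkers = n_walkers,
                 n_steps = n_steps, restart_every = restart_every,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full per-tissue analysis pipeline
#'
#' Per dataset: harmonize, fit, moderate, p-filter, coding-filter. Per
#' tissue: over-representation of the top fold-change genes with
#' cross-dataset term consistency; pathway expression scores; gene-level
#' consistency over the target pathways' members; guided and
#' topology-only walks with odds ratios and Louvain clusters (guides =
#' the consistent target-pathway genes, or the single dataset's member
#' DEGs when a tissue has only one dataset); thresholded PPI subgraph and
#' ECC modules over the consistent genes. All artifacts are written as
#' TSV/GraphML under `out_dir` together with a JSON manifest of
#' thresholds and seeds; reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with per-dataset DEG tables and per-tissue
#'   result bundles (`enrichment`, `consistent_terms`, `pathway_scores`,
#'   `consistency`, `odds_ratio`, `clusters`, `ppi_modules`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  collection <- config$gene_sets
  if (is.character(collection)) collection <- read_gmt(collection)
  network <- config$pathway_network
  if (is.character(network)) {
    el <- read_edge_list(network)
    network <- igraph::graph_from_data_frame(el, directed = FALSE)
  }
  ppi_tab <- config$ppi
  if (is.character(ppi_tab)) {
    ppi_g <- read_ppi_table(ppi_tab, threshold = config$ppi_threshold)
  } else if (!is.null(ppi_tab)) {
    ppi_g <- ppi_graph(ppi_tab, threshold = config$ppi_threshold)
  } else {
    ppi_g <- NULL
  }
  target_members <- unique(unlist(collection[config$target_pathways]))

  deg_tables <- list()
  meta <- list()
  for (i in seq_along(config$datasets)) {
    d <- config$datasets[[i]]
    ds <- if (!is.null(d$data)) d$data else {
      read_series_matrix(d$path, d$group_map,
                         is_log2 = if (is.null(d$is_log2)) NA else
                           d$is_log2)
    }
    ds <- harmonize(ds)
    deg <- diff_expression(ds, gene_map = d$gene_map)
    deg <- filter_degs(deg, p_thresh = config$p_thresh)
    deg <- coding_filter(deg)
    id <- ds$dataset_id
    deg_tables[[id]] <- deg
    meta[[id]] <- list(tissue = d$tissue, phenotype = d$phenotype)
    .write_tsv(deg, file.path(out_dir, sprintf("deg_%s.tsv", id)))
  }

  tissues <- unique(vapply(meta, `[[`, "", "tissue"))
  tissue_results <- list()
  for (tis in tissues) {
    ids <- names(meta)[vapply(meta, `[[`, "", "tissue") == tis]
    degs <- deg_tables[ids]
    enr <- lapply(degs, function(t) {
      top <- select_top(t, abs_lfc_thresh = config$lfc_thresh,
                        top_n = config$top_n)
      over_representation(top, collection)
    })
    cterms <- consistent_terms(enr, min_fraction = config$min_fraction)
    scores <- do.call(rbind, lapply(ids, function(id) {
      s <- pathway_scores(degs[[id]], collection)
      cbind(dataset = id, s)
    }))
    member_degs <- lapply(degs, function(t) {
      pathway_degs(t, target_members)
    })
    if (length(ids) >= 2) {
      cons <- consistency_scores(member_degs,
                                 min_fraction = config$min_fraction)
      guide_genes <- cons$gene[cons$consistent]
    } else {
      cons <- NULL
      guide_genes <- member_degs[[1]]$gene
    }
    walk_res <- NULL
    if (length(guide_genes) > 0 &&
        sum(vapply(collection, function(m) {
          length(intersect(guide_genes, m))
        }, numeric(1))) > 0) {
      cfg_g <- walk_config(config$n_walkers, config$n_steps,
                           config$restart_every, seed = config$seed)
      cfg_t <- walk_config(config$n_walkers, config$n_steps,
                           config$restart_every, seed = config$seed + 1L)
      gmass <- guide_scores(guide_genes, collection)
      gw <- guided_walk(network, gmass, cfg_g)
      tw <- topology_walk(network, cfg_t)
      ort <- odds_ratio(gw, tw)
      clus <- cluster_pathways(network, gw, seed = config$seed)
      walk_res <- list(guided = gw, topo = tw, odds_ratio = ort,
                       clusters = clus)
      .write_tsv(ort, file.path(out_dir,
                                sprintf("odds_ratio_%s.tsv", tis)))
      .write_tsv(clus, file.path(out_dir,
                                 sprintf("clusters_%s.tsv", tis)))
      top_ids <- ort$pathway_id[ort$or_gt_1]
      if (length(top_ids) > 1) {
        sub <- igraph::induced_subgraph(network, top_ids)
        write_graphml(sub, file.path(out_dir,
                                     sprintf("or_gt1_%s.graphml", tis)))
      }
    }
    ppi_res <- NULL
    if (!is.null(ppi_g) && length(guide_genes) > 0) {
      present <- intersect(guide_genes, igraph::V(ppi_g)$name)
      if (length(present) > 1) {
        sub <- igraph::induced_subgraph(ppi_g, present)
        sig <- if (length(config$target_pathways) >= 1)
          collection[[config$target_pathways[1]]] else character(0)
        met <- if (length(config$target_pathways) >= 2)
          collection[[config$target_pathways[2]]] else character(0)
        sub <- annotate_membership(sub, sig, met)
        mods <- fag_ec_modules(sub)
        ppi_res <- list(graph = sub, modules = mods)
        write_graphml(sub, file.path(out_dir,
                                     sprintf("ppi_%s.graphml", tis)))
        memb <- mods$membership
        .write_tsv(data.frame(protein = names(memb),
                              module = ifelse(is.na(memb), "unassigned",
                                              memb)),
                   file.path(out_dir, sprintf("ppi_modules_%s.tsv", tis)))
      }
    }
    .write_tsv(cterms, file.path(out_dir,
                                 sprintf("consistent_terms_%s.tsv", tis)))
    .write_tsv(scores, file.path(out_dir,
                                 sprintf("pathway_scores_%s.tsv", tis)))
    if (!is.null(cons)) {
      .write_tsv(cons, file.path(out_dir,
                                 sprintf("consistency_%s.tsv", tis)))
    }
    tissue_results[[tis]] <- list(
      enrichment = enr, consistent_terms = cterms,
      pathway_scores = scores, consistency = cons,
      guide_genes = guide_genes, walks = walk_res, ppi = ppi_res)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("crosspath")),
    seed = config$seed,
    thresholds = list(p = config$p_thresh, lfc = config$lfc_thresh,
                      top_n = config$top_n,
                      min_fraction = config$min_fraction,
                      ppi = config$ppi_threshold),
    walk = list(n_walkers = config$n_walkers, n_steps = config$n_steps,
                restart_every = config$restart_every),
    datasets = names(deg_tables), tissues = tissues)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(list(deg_tables = deg_tables, tissues = tissue_results,
                 manifest = manifest))
}
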