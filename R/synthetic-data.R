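# Synthetic multi-dataset cohorts with known ground truth. The generator
# emulates the structure of a multi-tissue microarray compendium: several
# case/control datasets per tissue, i.i.d. Gaussian noise on the log2
# scale, additive mean shifts on designated gene sets in affected samples,
# and optional linear-scale / negative-value export dialects so the
# harmonization path is exercised.

#' Specification of a synthetic case/control cohort
#'
#' @param n_datasets number of datasets in the cohort.
#' @param n_genes genes in the simulated universe.
#' @param n_affected,n_control samples per group per dataset (each >= 2 so
#'   the residual degrees of freedom allow variance estimation).
#' @param n_carrier carrier samples per dataset (kept out of the design).
#' @param perturbed_sets named list; each element is
#'   `list(genes = <character>, effect = <signed log2 shift>)`.
#' @param consistent_fraction proportion of datasets in which each
#'   perturbation is active; a perturbation is planted in
#'   `ceiling(consistent_fraction * n_datasets)` datasets chosen at random.
#' @param noise_sd log2-scale Gaussian noise standard deviation (> 0).
#' @param dialect `"log2"` (default), `"linear"` (2^x values) or
#'   `"linear_with_negatives"` (linear values shifted so the minimum is
#'   negative, as in background-subtracted arrays).
#' @param duplicate_probes emit two probes per gene with independent noise.
#' @param flip_fraction fraction of perturbed genes whose second probe
#'   receives the opposite-signed effect (exercises the multi-sign filter).
#' @param seed integer seed; generation is bit-reproducible under it.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_datasets = 3, n_genes = 1000, n_affected = 10,
                        n_control = 10, n_carrier = 0,
                        perturbed_sets = list(), consistent_fraction = 1,
                        noise_sd = 0.5, dialect = "log2",
                        duplicate_probes = FALSE, flip_fraction = 0,
                        seed = 1) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort spec: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (n_datasets < 1) fail("n_datasets", "must be >= 1")
  if (n_genes < 1) fail("n_genes", "must be >= 1")
  if (n_affected < 2) fail("n_affected", "must be >= 2")
  if (n_control < 2) fail("n_control", "must be >= 2")
  if (!(noise_sd > 0)) fail("noise_sd", "must be > 0")
  if (!(consistent_fraction > 0 && consistent_fraction <= 1)) {
    fail("consistent_fraction", "must be in (0, 1]")
  }
  if (!dialect %in% c("log2", "linear", "linear_with_negatives")) {
    fail("dialect", "must be one of log2, linear, linear_with_negatives")
  }
  if (flip_fraction < 0 || flip_fraction > 1) {
    fail("flip_fraction", "must be in [0, 1]")
  }
  universe <- gene_universe(n_genes)
  for (id in names(perturbed_sets)) {
    ps <- perturbed_sets[[id]]
    if (!all(c("genes", "effect") %in% names(ps))) {
      fail("perturbed_sets", sprintf("entry '%s' needs $genes and $effect",
                                     id))
    }
    if (!all(ps$genes %in% universe)) {
      fail("perturbed_sets",
           sprintf("entry '%s' names genes outside the universe", id))
    }
  }
  structure(
    list(n_datasets = as.integer(n_datasets), n_genes = as.integer(n_genes),
         n_affected = as.integer(n_affected),
         n_control = as.integer(n_control),
         n_carrier = as.integer(n_carrier),
         perturbed_sets = perturbed_sets,
         consistent_fraction = consistent_fraction, noise_sd = noise_sd,
         dialect = dialect, duplicate_probes = isTRUE(duplicate_probes),
         flip_fraction = flip_fraction, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Gene identifiers of the simulated universe
#' @param n_genes number of genes.
#' @return character vector `g0001`, `g0002`, ...
#' @export
gene_universe <- function(n_genes) {
  sprintf("g%05d", seq_len(n_genes))
}

#' Generate a synthetic case/control cohort
#'
#' Baseline log2 expression per gene is drawn once (uniform on 4-12) and
#' shared across datasets; each sample adds i.i.d. Gaussian noise. Each
#' perturbation is active in `ceiling(consistent_fraction * n_datasets)`
#' datasets, where it shifts the affected samples' means by the signed
#' effect. The export dialect optionally converts values to the linear
#' scale and/or shifts them negative.
#'
#' @param spec a [cohort_spec()].
#' @return list with `datasets` (list of [expression_dataset()]) and
#'   `truth` (per-dataset perturbed genes with signed effects, per-set
#'   expected direction and active datasets, and the probe -> gene map
#'   when probes are duplicated).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    genes <- gene_universe(spec$n_genes)
    baseline <- stats::runif(spec$n_genes, 4, 12)
    names(baseline) <- genes
    n_active <- ceiling(spec$consistent_fraction * spec$n_datasets)
    active <- lapply(spec$perturbed_sets, function(ps) {
      sort(sample.int(spec$n_datasets, n_active))
    })
    flipped <- lapply(spec$perturbed_sets, function(ps) {
      n_flip <- floor(spec$flip_fraction * length(ps$genes))
      if (n_flip > 0) sample(ps$genes, n_flip) else character(0)
    })
    n_samp <- spec$n_affected + spec$n_control + spec$n_carrier
    groups <- rep(c("affected", "control", "carrier"),
                  c(spec$n_affected, spec$n_control, spec$n_carrier))
    datasets <- vector("list", spec$n_datasets)
    truth_genes <- vector("list", spec$n_datasets)
    for (d in seq_len(spec$n_datasets)) {
      sample_ids <- sprintf("D%02d_%s%02d", d,
                            c(rep("aff", spec$n_affected),
                              rep("ctl", spec$n_control),
                              rep("car", spec$n_carrier)),
                            c(seq_len(spec$n_affected),
                              seq_len(spec$n_control),
                              seq_len(max(spec$n_carrier, 0))[
                                seq_len(spec$n_carrier)]))
      grp <- stats::setNames(groups, sample_ids)
      signal <- matrix(baseline, nrow = spec$n_genes, ncol = n_samp,
                       dimnames = list(genes, sample_ids))
      eff <- stats::setNames(numeric(spec$n_genes), genes)
      for (id in names(spec$perturbed_sets)) {
        if (!(d %in% active[[id]])) next
        ps <- spec$perturbed_sets[[id]]
        eff[ps$genes] <- eff[ps$genes] + ps$effect
      }
      aff_cols <- which(grp == "affected")
      signal[, aff_cols] <- signal[, aff_cols] + eff
      if (spec$duplicate_probes) {
        probes <- c(paste0(genes, "_p1"), paste0(genes, "_p2"))
        eff2 <- eff
        flip_all <- unlist(flipped, use.names = FALSE)
        eff2[flip_all] <- -eff2[flip_all]
        signal2 <- matrix(baseline, nrow = spec$n_genes, ncol = n_samp,
                          dimnames = list(genes, sample_ids))
        signal2[, aff_cols] <- signal2[, aff_cols] + eff2
        m <- rbind(signal, signal2)
        rownames(m) <- probes
        m <- m + matrix(stats::rnorm(length(m), sd = spec$noise_sd),
                        nrow = nrow(m))
      } else {
        m <- signal + matrix(stats::rnorm(length(signal),
                                          sd = spec$noise_sd),
                             nrow = spec$n_genes)
      }
      is_log2 <- TRUE
      if (spec$dialect != "log2") {
        m <- 2^m
        is_log2 <- FALSE
        if (spec$dialect == "linear_with_negatives") {
          m <- m - (min(m) + 1)
        }
      }
      truth_genes[[d]] <- data.frame(gene = names(eff)[eff != 0],
                                     effect = unname(eff[eff != 0]),
                                     stringsAsFactors = FALSE)
      datasets[[d]] <- expression_dataset(
        m, grp, is_log2 = is_log2, dataset_id = sprintf("synthetic_%02d", d))
    }
    gene_map <- NULL
    if (spec$duplicate_probes) {
      gene_map <- stats::setNames(rep(genes, 2),
                                  c(paste0(genes, "_p1"),
                                    paste0(genes, "_p2")))
    }
    truth <- list(
      perturbed = truth_genes,
      set_direction = vapply(spec$perturbed_sets,
                             function(ps) sign(ps$effect), numeric(1)),
      active_datasets = active,
      flipped_genes = flipped,
      gene_map = gene_map)
    list(datasets = datasets, truth = truth)
  })
}

#' Generate a collection of synthetic pathways
#'
#' Draws `n_pathways` gene sets with sizes uniform in `size_range`. With a
#' positive `overlap_fraction`, consecutive sets in the collection are
#' designated neighbors and constructed to share enough genes that their
#' Jaccard index is at least `overlap_fraction`; with 0, sets are pairwise
#' disjoint (requiring a large enough universe).
#'
#' @param n_pathways number of sets.
#' @param size_range integer pair (min, max) set size.
#' @param universe character vector of gene IDs to draw from.
#' @param overlap_fraction minimum Jaccard index between neighbor sets.
#' @param seed integer seed.
#' @return a [gene_set_collection()]; neighbor pairs in attribute
#'   `neighbors`.
#' @export
generate_pathways <- function(n_pathways, size_range, universe,
                              overlap_fraction = 0, seed = 1) {
  if (length(universe) == 0) {
    stop("configuration error: empty gene universe", call. = FALSE)
  }
  if (max(size_range) > length(universe)) {
    stop("configuration error: size_range exceeds universe size",
         call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("configuration error: overlap_fraction must be in [0, 1)",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    size_choices <- seq(size_range[1], size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_pathways,
                                     replace = TRUE)]
    if (overlap_fraction == 0 && sum(sizes) > length(universe)) {
      stop("configuration error: universe too small for disjoint sets of ",
           "the requested sizes", call. = FALSE)
    }
    unused <- sample(universe)
    take_fresh <- function(k) {
      if (k > length(unused)) {
        # recycle: sample from the full universe once fresh genes run out
        return(sample(universe, k))
      }
      out <- unused[seq_len(k)]
      unused <<- unused[-seq_len(k)]
      out
    }
    sets <- vector("list", n_pathways)
    sets[[1]] <- take_fresh(sizes[1])
    if (n_pathways > 1) {
      for (i in 2:n_pathways) {
        s_prev <- sizes[i - 1]
        s_i <- sizes[i]
        # Jaccard o/(s_prev + s_i - o) >= f  =>  o >= f(s_prev+s_i)/(1+f)
        o <- ceiling(overlap_fraction * (s_prev + s_i) /
                       (1 + overlap_fraction))
        if (o > min(s_prev, s_i)) {
          stop("configuration error: requested overlap_fraction ",
               "infeasible for set sizes ", s_prev, " and ", s_i,
               call. = FALSE)
        }
        shared <- if (o > 0) sample(sets[[i - 1]], o) else character(0)
        sets[[i]] <- c(shared, take_fresh(s_i - o))
      }
    }
    names(sets) <- sprintf("pw%03d", seq_len(n_pathways))
    coll <- gene_set_collection(sets, universe = universe)
    attr(coll, "neighbors") <- if (n_pathways > 1 && overlap_fraction > 0) {
      cbind(names(sets)[-n_pathways], names(sets)[-1])
    } else {
      NULL
    }
    coll
  })
}

#' Build a pathway-to-pathway network from shared gene membership
#'
#' Undirected simple graph on the collection's set IDs with an edge
#' whenever two sets share at least `min_shared` genes (`min_shared = 0`
#' yields the complete graph). If the shared-membership graph is
#' disconnected, a spanning backbone of extra edges joins the components
#' (edge attribute `backbone`, graph attribute `backbone_added`) so walks
#' can reach every pathway.
#'
#' @param collection a [gene_set_collection()].
#' @param min_shared minimum shared-gene count for a native edge.
#' @param seed seed for the backbone attachment choice.
#' @return an `igraph` graph, vertices named by set ID.
#' @export
generate_pathway_network <- function(collection, min_shared = 1, seed = 1) {
  if (length(collection) == 0) {
    stop("configuration error: empty pathway collection", call. = FALSE)
  }
  ids <- names(collection)
  n <- length(ids)
  from <- character(0); to <- character(0)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (length(intersect(collection[[i]], collection[[j]])) >=
            min_shared) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = ids))
  if (igraph::ecount(g) > 0) igraph::E(g)$backbone <- FALSE
  comps <- igraph::components(g)
  backbone_added <- comps$no > 1
  if (backbone_added) {
    withr::with_seed(seed, {
      reps <- vapply(seq_len(comps$no), function(k) {
        members <- ids[comps$membership == k]
        sample(members, 1)
      }, "")
      extra <- cbind(reps[-length(reps)], reps[-1])
      g <- igraph::add_edges(g, t(extra), backbone = TRUE)
    })
  }
  g <- igraph::set_graph_attr(g, "backbone_added", backbone_added)
  g
}

#' Generate a synthetic PPI score table with planted modules
#'
#' Pairs within a module are connected densely with high combined scores;
#' pairs across modules sparsely with low scores, so thresholding at the
#' usual high-confidence cutoff leaves only the planted modules.
#'
#' @param genes character vector of protein/gene symbols.
#' @param module_assignments named vector gene -> module id.
#' @param intra_score_range,inter_score_range score ranges within [0, 1]
#'   for intra- and inter-module edges.
#' @param intra_density,inter_density edge probabilities within / across
#'   modules.
#' @param seed integer seed.
#' @return data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @export
generate_ppi_table <- function(genes, module_assignments,
                               intra_score_range = c(0.75, 0.99),
                               inter_score_range = c(0.15, 0.5),
                               intra_density = 1, inter_density = 0.1,
                               seed = 1) {
  rng <- c(intra_score_range, inter_score_range)
  if (any(rng < 0 | rng > 1)) {
    stop("configuration error: score ranges must lie within [0, 1]",
         call. = FALSE)
  }
  empty <- data.frame(protein1 = character(0), protein2 = character(0),
                      combined_score = numeric(0))
  if (length(genes) < 2) return(empty)
  withr::with_seed(seed, {
    pairs <- utils::combn(sort(genes), 2)
    p1 <- pairs[1, ]; p2 <- pairs[2, ]
    same <- module_assignments[p1] == module_assignments[p2] &
      !is.na(module_assignments[p1]) & !is.na(module_assignments[p2])
    keep <- stats::runif(length(p1)) <
      ifelse(same, intra_density, inter_density)
    score <- ifelse(same,
                    stats::runif(length(p1), intra_score_range[1],
                                 intra_score_range[2]),
                    stats::runif(length(p1), inter_score_range[1],
                                 inter_score_range[2]))
    out <- data.frame(protein1 = p1[keep], protein2 = p2[keep],
                      combined_score = round(score[keep], 3),
                      stringsAsFactors = FALSE, row.names = NULL)
    out
  })
}
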