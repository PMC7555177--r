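# Gene-set enrichment: one-sided hypergeometric over-representation with
# an Enrichr-style combined score, the unweighted (Kolmogorov-Smirnov
# running sum) form of GSEA with permutation p-values, cross-dataset term
# consistency, and category percentage rollups.

#' Over-representation analysis against a gene-set collection
#'
#' For each set, tests whether the query list overlaps the set more than
#' expected under hypergeometric sampling from the universe (one-sided,
#' P(overlap >= observed)). The combined score is `-ln(p) * z`, where `z`
#' is the standardized deviation of the observed overlap from its
#' hypergeometric mean. Query genes outside the universe are dropped (the
#' count is reported in attribute `n_dropped`).
#'
#' @param gene_list character vector of query genes.
#' @param collection a [gene_set_collection()].
#' @param universe scorable gene universe; defaults to the collection's
#'   universe attribute, else the union of its sets.
#' @param p_select selection cutoff for the `selected` flag (default 0.05).
#' @return data.frame with columns `set_id`, `hits`, `set_size`,
#'   `expected`, `odds_enrichment`, `p_value`, `z`, `combined_score`,
#'   `selected`, sorted by ascending p.
#' @export
over_representation <- function(gene_list, collection,
                                universe = NULL, p_select = 0.05) {
  if (is.null(universe)) universe <- attr(collection, "universe")
  if (is.null(universe)) universe <- unique(unlist(collection))
  gene_list <- unique(gene_list)
  in_universe <- gene_list %in% universe
  n_dropped <- sum(!in_universe)
  gene_list <- gene_list[in_universe]
  if (length(gene_list) == 0) {
    warning("empty query gene list after universe restriction")
    out <- data.frame(set_id = character(0), hits = integer(0),
                      set_size = integer(0), expected = numeric(0),
                      odds_enrichment = numeric(0), p_value = numeric(0),
                      z = numeric(0), combined_score = numeric(0),
                      selected = logical(0))
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]], universe)
    K <- length(members)
    hits <- length(intersect(gene_list, members))
    # one-sided tail P(X >= hits) for X ~ Hypergeom(N, K, n)
    p <- stats::phyper(hits - 1, K, N - K, n, lower.tail = FALSE)
    mu <- n * K / N
    sd_h <- sqrt(mu * (N - K) / N * (N - n) / max(N - 1, 1))
    z <- if (sd_h > 0) (hits - mu) / sd_h else 0
    data.frame(set_id = id, hits = hits, set_size = K, expected = mu,
               odds_enrichment = if (mu > 0) hits / mu else NA_real_,
               p_value = p, z = z,
               combined_score = -log(p) * z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$p_value < p_select
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

# running-sum statistic for the unweighted KS-form GSEA, given hit
# positions (logical or index vector) in a ranked list of length N
gsea_running_stat <- function(is_hit, N = length(is_hit)) {
  k <- sum(is_hit)
  inc <- ifelse(is_hit, sqrt((N - k) / k), -sqrt(k / (N - k)))
  rs <- cumsum(inc)
  i_ext <- which.max(abs(rs))
  list(statistic = rs[i_ext], position = i_ext, running_sum = rs)
}

#' Unweighted gene-set enrichment on a ranked gene list
#'
#' Walks the list from top to bottom, adding `sqrt((N-k)/k)` at set members
#' and subtracting `sqrt(k/(N-k))` at non-members; the statistic is the
#' signed extreme deviation of this running sum (positive when the set
#' accumulates at the top, negative at the bottom; the sum returns to zero
#' at the end of the list). Significance is assessed by permuting the hit
#' positions: exhaustively over all `choose(N, k)` placements when that
#' number is at most `max_exhaustive`, otherwise by `n_perm` random
#' placements with the +1 correction (so p is never exactly 0).
#'
#' @param ranked_genes character vector sorted by expression score, no
#'   duplicates.
#' @param gene_set character vector; restricted to the ranked genes.
#' @param n_perm number of random permutations (default 1000).
#' @param max_exhaustive enumerate all placements when `choose(N, k)` is at
#'   most this (default 50000).
#' @param seed integer seed for the permutation draw.
#' @return one-row data.frame: `statistic`, `p_value`, `hits`, `expected`
#'   (hits expected above the extremum under uniform placement),
#'   `extremum_position`, `exhaustive`.
#' @export
unweighted_gsea <- function(ranked_genes, gene_set, n_perm = 1000,
                            max_exhaustive = 50000, seed = 1) {
  if (anyDuplicated(ranked_genes)) {
    stop("ranked gene list contains duplicates", call. = FALSE)
  }
  is_hit <- ranked_genes %in% gene_set
  N <- length(ranked_genes)
  k <- sum(is_hit)
  if (k == 0 || k == N) {
    stop("undefined-statistic error: gene set and ranked list overlap in ",
         k, " of ", N, " genes", call. = FALSE)
  }
  obs <- gsea_running_stat(is_hit, N)
  stat_for <- function(pos) {
    hit <- logical(N)
    hit[pos] <- TRUE
    gsea_running_stat(hit, N)$statistic
  }
  n_comb <- choose(N, k)
  if (n_comb <= max_exhaustive) {
    placements <- utils::combn(N, k)
    perm_stats <- apply(placements, 2, stat_for)
    p <- mean(abs(perm_stats) >= abs(obs$statistic) - 1e-12)
    exhaustive <- TRUE
  } else {
    perm_stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_for(sample.int(N, k)),
             numeric(1))
    })
    p <- (1 + sum(abs(perm_stats) >= abs(obs$statistic) - 1e-12)) /
      (n_perm + 1)
    exhaustive <- FALSE
  }
  data.frame(statistic = obs$statistic, p_value = p, hits = k,
             expected = k * obs$position / N,
             extremum_position = obs$position, exhaustive = exhaustive)
}

#' Terms selected consistently across datasets
#'
#' A term is kept when it is flagged `selected` (p below the selection
#' cutoff) in at least `ceiling(min_fraction * n_datasets)` of the
#' per-dataset enrichment results.
#'
#' @param results named list of [over_representation()] data.frames, one
#'   per dataset.
#' @param min_fraction minimum fraction of datasets (default 1/3).
#' @return data.frame `set_id`, `n_selected`, `n_datasets`, `kept`, with
#'   the per-dataset p-value matrix in attribute `p_matrix`.
#' @export
consistent_terms <- function(results, min_fraction = 1/3) {
  if (length(results) < 1) {
    stop("consistent_terms needs at least one dataset result",
         call. = FALSE)
  }
  n <- length(results)
  need <- ceiling(min_fraction * n)
  ids <- sort(unique(unlist(lapply(results, `[[`, "set_id"))))
  pmat <- sapply(results, function(r) {
    stats::setNames(r$p_value, r$set_id)[ids]
  })
  pmat <- matrix(pmat, nrow = length(ids),
                 dimnames = list(ids, names(results)))
  selmat <- sapply(results, function(r) {
    stats::setNames(r$selected, r$set_id)[ids]
  })
  selmat <- matrix(selmat, nrow = length(ids))
  n_sel <- rowSums(selmat, na.rm = TRUE)
  out <- data.frame(set_id = ids, n_selected = n_sel, n_datasets = n,
                    kept = n_sel >= need, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(-out$n_selected, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_matrix") <- pmat
  attr(out, "n_required") <- need
  out
}

#' Percentage occurrence of term categories
#'
#' @param term_list character vector of selected term IDs.
#' @param category_map named character vector term -> category; unmapped
#'   terms are counted under `"unassigned"`.
#' @return data.frame `category`, `n_terms`, `percent` (100 * terms in
#'   category / total terms).
#' @export
rollup_categories <- function(term_list, category_map) {
  if (length(term_list) == 0) {
    return(data.frame(category = character(0), n_terms = integer(0),
                      percent = numeric(0)))
  }
  cats <- category_map[term_list]
  cats[is.na(cats)] <- "unassigned"
  tab <- table(cats)
  out <- data.frame(category = names(tab), n_terms = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(term_list),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$percent, out$category), , drop = FALSE]
}
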