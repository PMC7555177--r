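# Pathway-level expression characterization: isolate the differentially
# expressed members of a pathway, summarize their fold-change distribution
# into rateFC / normMeanFC / combined fold change, and flag genes whose
# direction of change is consistent across datasets.

#' Differentially expressed members of a pathway
#'
#' @param deg_table a p-filtered `deg_table`.
#' @param pathway pathway ID to look up in `collection`, or directly a
#'   character vector of member genes.
#' @param collection a [gene_set_collection()] (needed when `pathway` is an
#'   ID).
#' @return the rows of `deg_table` whose gene belongs to the pathway.
#' @export
pathway_degs <- function(deg_table, pathway, collection = NULL) {
  members <- if (length(pathway) == 1 && !is.null(collection)) {
    if (!pathway %in% names(collection)) {
      stop("lookup error: unknown pathway '", pathway, "'", call. = FALSE)
    }
    collection[[pathway]]
  } else {
    pathway
  }
  out <- deg_table[deg_table$gene %in% members, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of a pathway's genes that are over-expressed
#'
#' @param member_degs DEG rows of the pathway (see [pathway_degs()]).
#' @param n_total total pathway genes in the measured universe.
#' @return `rateFC` in [0, 1]: over-expressed member DEGs / `n_total`.
#' @export
rate_fc <- function(member_degs, n_total) {
  if (n_total <= 0) {
    stop("degenerate-pathway error: pathway has no measured genes",
         call. = FALSE)
  }
  sum(member_degs$log2FC > 0) / n_total
}

#' Weighted mean of the normalized fold-change histogram
#'
#' Member log2 fold changes are clipped to `[-range_limit, range_limit]`,
#' binned into `n_bins` equal-width bins, the bin frequencies normalized to
#' sum to one, and the weighted mean of the bin centers returned. As
#' `n_bins` grows this converges to the arithmetic mean of the clipped
#' fold changes.
#'
#' @param member_degs DEG rows of the pathway; must be non-empty.
#' @param n_bins number of histogram bins (default 20).
#' @param range_limit half-width of the histogram range in log2 units
#'   (default 4).
#' @return `normMeanFC` in `[-range_limit, range_limit]`.
#' @export
norm_mean_fc <- function(member_degs, n_bins = 20, range_limit = 4) {
  x <- member_degs$log2FC
  if (length(x) == 0) {
    stop("normMeanFC undefined: pathway has no member DEGs", call. = FALSE)
  }
  x <- pmin(pmax(x, -range_limit), range_limit)
  breaks <- seq(-range_limit, range_limit, length.out = n_bins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  freq <- tabulate(idx, nbins = n_bins)
  freq <- freq / sum(freq)
  sum(centers * freq)
}

#' Combined pathway fold change on the [0, 2] scale
#'
#' `combinedFC = rateFC + clip((normMeanFC + range_limit) /
#' (2 * range_limit), 0, 1)`. Values in (1, 2] indicate that the majority
#' of participating genes are over-expressed; values in [0, 1) an overall
#' under-expression; a balanced pathway (half the genes up, zero mean
#' shift) scores exactly 1.
#'
#' @param rateFC value from [rate_fc()].
#' @param normMeanFC value from [norm_mean_fc()].
#' @param range_limit the histogram half-width used for `normMeanFC`.
#' @return `combinedFC` in [0, 2].
#' @export
combined_fc <- function(rateFC, normMeanFC, range_limit = 4) {
  m <- (normMeanFC + range_limit) / (2 * range_limit)
  m <- pmin(pmax(m, 0), 1)
  rateFC + m
}

#' Score every pathway of a collection for one dataset
#'
#' @param deg_table a p-filtered `deg_table` for one dataset.
#' @param collection a [gene_set_collection()].
#' @param universe measured gene universe (defaults to the collection's);
#'   pathway denominators count members inside it.
#' @param n_bins,range_limit histogram parameters for [norm_mean_fc()].
#' @return data.frame `pathway_id`, `n_deg`, `n_total`, `rateFC`,
#'   `normMeanFC`, `combinedFC` (NA scores for pathways without member
#'   DEGs, reported as unscored).
#' @export
pathway_scores <- function(deg_table, collection, universe = NULL,
                           n_bins = 20, range_limit = 4) {
  if (is.null(universe)) universe <- attr(collection, "universe")
  if (is.null(universe)) universe <- unique(unlist(collection))
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]], universe)
    n_total <- length(members)
    md <- pathway_degs(deg_table, members)
    if (n_total == 0) {
      return(data.frame(pathway_id = id, n_deg = 0L, n_total = 0L,
                        rateFC = NA_real_, normMeanFC = NA_real_,
                        combinedFC = NA_real_, stringsAsFactors = FALSE))
    }
    r <- rate_fc(md, n_total)
    if (nrow(md) == 0) {
      nm <- NA_real_
      cf <- NA_real_
    } else {
      nm <- norm_mean_fc(md, n_bins = n_bins, range_limit = range_limit)
      cf <- combined_fc(r, nm, range_limit = range_limit)
    }
    data.frame(pathway_id = id, n_deg = nrow(md), n_total = n_total,
               rateFC = r, normMeanFC = nm, combinedFC = cf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-dataset consistency of gene-level differential expression
#'
#' For every gene appearing in at least one DEG table, counts the datasets
#' in which it is up- and down-regulated. The score is the count of the
#' majority sign; a gene is consistent when that score reaches
#' `max(2, ceiling(min_fraction * n_datasets))`. Conflicting signs in
#' other datasets are allowed and do not disqualify the gene; they only
#' fail to add to its score.
#'
#' @param per_dataset_degs named list (length >= 2) of `deg_table`s, one
#'   per dataset.
#' @param min_fraction minimum fraction of datasets (default 1/3).
#' @return data.frame `gene`, `n_up`, `n_down`, `majority_sign` (0 on a
#'   tie), `score`, `consistent`; the gene-by-dataset signed log2FC matrix
#'   is in attribute `lfc_matrix`.
#' @export
consistency_scores <- function(per_dataset_degs, min_fraction = 1/3) {
  n <- length(per_dataset_degs)
  if (n < 2) {
    stop("consistency_scores needs at least 2 datasets", call. = FALSE)
  }
  if (is.null(names(per_dataset_degs))) {
    names(per_dataset_degs) <- paste0("dataset", seq_len(n))
  }
  genes <- sort(unique(unlist(lapply(per_dataset_degs, `[[`, "gene"))))
  need <- max(2, ceiling(min_fraction * n))
  lfc <- matrix(NA_real_, nrow = length(genes), ncol = n,
                dimnames = list(genes, names(per_dataset_degs)))
  for (i in seq_len(n)) {
    t_i <- per_dataset_degs[[i]]
    lfc[t_i$gene, i] <- t_i$log2FC
  }
  n_up <- rowSums(lfc > 0, na.rm = TRUE)
  n_down <- rowSums(lfc < 0, na.rm = TRUE)
  score <- pmax(n_up, n_down)
  majority <- sign(n_up - n_down)
  out <- data.frame(gene = genes, n_up = n_up, n_down = n_down,
                    majority_sign = majority, score = score,
                    consistent = score >= need,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lfc_matrix") <- lfc
  attr(out, "n_required") <- need
  out
}
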