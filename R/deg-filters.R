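# The probe-to-gene filtering cascade applied after differential
# expression: raw p-value cutoff, removal of genes whose surviving probes
# disagree in fold-change sign, lowest-p deduplication of same-sign
# probes, biotype/prefix exclusion, and fold-change top-N selection.

#' Filter a DEG table: p cutoff, multi-sign removal, lowest-p dedup
#'
#' Rows with `p_value >= p_thresh` are dropped first. Genes whose surviving
#' probes disagree in `log2FC` sign are then removed entirely; among
#' same-sign duplicates, the row with the lowest p-value is kept (ties
#' broken by larger absolute fold change, then probe ID).
#'
#' @param table a `deg_table` (possibly multiple probes per gene).
#' @param p_thresh raw p-value cutoff (default 0.05, strict `<`).
#' @return a `deg_table` with one row per gene.
#' @export
filter_degs <- function(table, p_thresh = 0.05) {
  keep <- table$p_value < p_thresh
  t2 <- table[keep, , drop = FALSE]
  if (nrow(t2) == 0) {
    rownames(t2) <- NULL
    return(t2)
  }
  sgn <- split(sign(t2$log2FC), t2$gene)
  multi_sign <- names(sgn)[vapply(sgn, function(s) {
    any(s > 0) && any(s < 0)
  }, logical(1))]
  t2 <- t2[!(t2$gene %in% multi_sign), , drop = FALSE]
  if (nrow(t2) == 0) {
    rownames(t2) <- NULL
    return(t2)
  }
  ord <- order(t2$gene, t2$p_value, -abs(t2$log2FC), t2$probe)
  t2 <- t2[ord, , drop = FALSE]
  t2 <- t2[!duplicated(t2$gene), , drop = FALSE]
  rownames(t2) <- NULL
  t2
}

# biotypes excluded from the coding filter
.noncoding_biotypes <- c(
  "non_coding", "ncRNA", "lncRNA", "microRNA", "miRNA", "miscRNA",
  "misc_RNA", "snRNA", "snoRNA", "uncharacterized"
)

#' Restrict a DEG table to protein-coding, characterized genes
#'
#' Drops rows whose biotype annotation marks them as non-coding RNA,
#' microRNA, misc RNA, small nuclear/nucleolar RNA or uncharacterized, and
#' rows whose gene symbol starts with the uncharacterized-gene prefixes
#' LOC, FLJ or RP.
#'
#' The literal RP-prefix rule also removes ribosomal-protein symbols
#' (RPL/RPS); `rp_prefix_mode = "clone_only"` instead restricts the rule to
#' RP11-style clone identifiers (RP followed by digits and a hyphen).
#'
#' @param table a `deg_table`.
#' @param biotype optional named character vector gene -> biotype.
#' @param rp_prefix_mode `"literal"` (default) or `"clone_only"`.
#' @return filtered `deg_table`.
#' @export
coding_filter <- function(table, biotype = NULL,
                          rp_prefix_mode = c("literal", "clone_only")) {
  rp_prefix_mode <- match.arg(rp_prefix_mode)
  drop <- rep(FALSE, nrow(table))
  if (!is.null(biotype)) {
    bt <- biotype[table$gene]
    drop <- drop | (!is.na(bt) & bt %in% .noncoding_biotypes)
  }
  rp_pattern <- if (rp_prefix_mode == "literal") "^RP" else "^RP[0-9]+-"
  drop <- drop | grepl("^LOC", table$gene) | grepl("^FLJ", table$gene) |
    grepl(rp_pattern, table$gene)
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top genes by absolute fold change
#'
#' Keeps rows with `|log2FC|` strictly greater than `abs_lfc_thresh`, then
#' returns at most `top_n` gene IDs ordered by descending absolute fold
#' change (ties broken by ascending p-value, then gene ID).
#'
#' @param table a p-filtered `deg_table`.
#' @param abs_lfc_thresh absolute log2 fold-change cutoff (default 0.585,
#'   i.e. 1.5-fold; strict `>`).
#' @param top_n cap on the number of genes returned (default 500).
#' @return character vector of gene IDs.
#' @export
select_top <- function(table, abs_lfc_thresh = 0.585, top_n = 500) {
  t2 <- table[abs(table$log2FC) > abs_lfc_thresh, , drop = FALSE]
  if (nrow(t2) == 0) return(character(0))
  ord <- order(-abs(t2$log2FC), t2$p_value, t2$gene)
  utils::head(t2$gene[ord], top_n)
}

#' Cross-dataset DEG overlap counts
#'
#' Pairwise and k-way intersection counts of the gene sets in a list of DEG
#' tables, both requiring matching fold-change sign and ignoring direction.
#'
#' @param tables named list (length >= 2) of `deg_table`s.
#' @return list with `pairwise` (data.frame: dataset pair, `n_same_sign`,
#'   `n_any_sign`) and `kway` (counts `n_same_sign`, `n_any_sign` of genes
#'   present in every table).
#' @export
deg_overlap <- function(tables) {
  if (length(tables) < 2) {
    stop("deg_overlap needs at least 2 DEG tables", call. = FALSE)
  }
  if (is.null(names(tables))) {
    names(tables) <- paste0("dataset", seq_along(tables))
  }
  signed <- lapply(tables, function(t) {
    stats::setNames(sign(t$log2FC), t$gene)
  })
  pair_count <- function(a, b) {
    common <- intersect(names(a), names(b))
    c(n_same_sign = sum(a[common] == b[common]), n_any_sign = length(common))
  }
  pairs <- utils::combn(names(tables), 2)
  pw <- t(apply(pairs, 2, function(p) {
    pair_count(signed[[p[1]]], signed[[p[2]]])
  }))
  pairwise <- data.frame(dataset_a = pairs[1, ], dataset_b = pairs[2, ],
                         pw, stringsAsFactors = FALSE)
  common <- Reduce(intersect, lapply(signed, names))
  same <- if (length(common)) {
    sgn <- vapply(signed, function(s) s[common], numeric(length(common)))
    if (length(common) == 1) sgn <- matrix(sgn, nrow = 1)
    sum(apply(sgn, 1, function(r) all(r == r[1])))
  } else {
    0L
  }
  list(pairwise = pairwise,
       kway = c(n_same_sign = same, n_any_sign = length(common)))
}
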