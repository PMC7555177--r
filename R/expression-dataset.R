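#' Expression dataset container
#'
#' Bundles a gene-by-sample expression matrix with its sample group labels
#' and a flag recording whether values are on the log2 scale. This is the
#' unit that flows through harmonization and differential expression.
#'
#' @param values numeric matrix, genes in rows (rownames = gene/probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param groups named character vector mapping every sample ID to one of
#'   `"affected"`, `"control"`, `"carrier"`.
#' @param is_log2 logical flag; `TRUE` when `values` are log2 intensities.
#' @param dataset_id optional identifier carried through to outputs.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `groups`, `is_log2`, `dataset_id`.
#' @export
expression_dataset <- function(values, groups, is_log2 = TRUE,
                               dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have row (gene) and column (sample) names",
         call. = FALSE)
  }
  groups <- unlist(groups)
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing) > 0) {
    stop("no group label for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("affected", "control", "carrier"))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(values = values, groups = groups, is_log2 = isTRUE(is_log2),
         dataset_id = as.character(dataset_id)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset '%s'> %d genes x %d samples (%s scale)\n",
    x$dataset_id, nrow(x$values), ncol(x$values),
    if (x$is_log2) "log2" else "linear"))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# samples used in the two-group contrast; carriers are retained in the
# object but never enter the design
design_samples <- function(dataset) {
  names(dataset$groups)[dataset$groups %in% c("affected", "control")]
}
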