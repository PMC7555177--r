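# IO for the tab-delimited exchange dialects used throughout the pipeline:
# GEO Series Matrix expression tables, GMT gene sets, 2-column edge lists,
# sample-group maps and 3-column PPI score tables.

#' Read a GEO Series Matrix file
#'
#' Parses the tab-delimited table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Metadata lines (prefixed `!`) outside the
#' table block are ignored. Blank or `NA`/`null` cells become `NA` and are
#' reported via an attribute.
#'
#' @param path path to a series-matrix-format text file.
#' @param group_map named character vector (or path to a 2-column TSV,
#'   sample_id then group) mapping samples to
#'   `"affected"`/`"control"`/`"carrier"`.
#' @param is_log2 scale flag for the stored values; if `NA` (default) it is
#'   inferred with [detect_log_scale()].
#' @param dataset_id identifier for the resulting dataset; defaults to the
#'   file name.
#' @return An [expression_dataset()]. Carrier samples are retained in the
#'   object; downstream differential expression excludes them.
#' @export
read_series_matrix <- function(path, group_map, is_log2 = NA,
                               dataset_id = NULL) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin) {
    stop("series matrix format error: expected exactly one table block ",
         "delimited by !series_matrix_table_begin/_end in ", path,
         call. = FALSE)
  }
  body <- lines[(begin + 1):(end - 1)]
  if (length(body) < 2) {
    stop("series matrix format error: empty table block in ", path,
         call. = FALSE)
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncol_expect <- length(cells[[1]])
  widths <- lengths(cells)
  if (any(widths != ncol_expect)) {
    bad <- which(widths != ncol_expect)[1]
    stop(sprintf(
      "series matrix format error: ragged row at line %d of %s",
      begin + bad, path), call. = FALSE)
  }
  header <- gsub("\"", "", cells[[1]])
  sample_ids <- header[-1]
  rows <- cells[-1]
  gene_ids <- gsub("\"", "", vapply(rows, `[[`, "", 1L))
  raw <- unlist(lapply(rows, `[`, -1L), use.names = FALSE)
  raw[raw %in% c("", "NA", "na", "null", "NULL")] <- NA_character_
  vals <- suppressWarnings(as.numeric(raw))
  bad_cell <- !is.na(raw) & is.na(vals)
  if (any(bad_cell)) {
    stop("series matrix format error: non-numeric cell value '",
         raw[which(bad_cell)[1]], "' in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = length(gene_ids), ncol = length(sample_ids),
              byrow = TRUE, dimnames = list(gene_ids, sample_ids))
  if (is.character(group_map) && length(group_map) == 1 &&
      is.null(names(group_map)) && file.exists(group_map)) {
    group_map <- read_group_map(group_map)
  }
  if (is.null(dataset_id)) dataset_id <- sub("\\.[^.]*$", "", basename(path))
  n_missing <- sum(is.na(m))
  if (is.na(is_log2)) {
    is_log2 <- detect_log_scale(m)
  }
  ds <- expression_dataset(m, group_map, is_log2 = is_log2,
                           dataset_id = dataset_id)
  attr(ds, "n_missing") <- n_missing
  ds
}

#' Write an expression dataset as a GEO Series Matrix file
#'
#' Inverse of [read_series_matrix()] for the synthetic dialect: `!`-prefixed
#' header lines, then the tab-delimited table between the begin/end markers.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(dataset, path) {
  m <- dataset$values
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("!Series_title\t\"%s\"", dataset$dataset_id),
    sprintf("!Series_scale\t\"%s\"", if (dataset$is_log2) "log2" else "linear"),
    "!series_matrix_table_begin"), con)
  writeLines(paste(c("ID_REF", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = "\t")
  })
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Read a sample-group map
#'
#' Two-column tab-delimited file: sample_id, group.
#' @param path path to the TSV.
#' @return named character vector sample -> group.
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("sample_id", "group"))
  stats::setNames(df$group, df$sample_id)
}

#' @rdname read_group_map
#' @param groups named character vector to write.
#' @export
write_group_map <- function(groups, path) {
  utils::write.table(data.frame(names(groups), unname(groups)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set id, description, then member genes, tab-separated.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `names` attribute table; see [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) {
    stop("GMT format error: line ", which(short)[1],
         " has fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  gene_set_collection(stats::setNames(sets, ids),
                      descriptions = stats::setNames(desc, ids))
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection` (or plain named list of gene
#'   vectors) to write.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(collection),
                                             names(collection))
  lines <- vapply(names(collection), function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene set collection
#'
#' A named list of gene-ID character vectors with optional per-set
#' descriptions and an optional scoring universe.
#'
#' @param sets named list of character vectors (set id -> member genes).
#' @param descriptions optional named character vector of set descriptions.
#' @param universe optional character vector of scorable genes; when given,
#'   sets are restricted to it and emptied sets dropped.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("`sets` must be a uniquely named list", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, y = universe)
    sets <- sets[lengths(sets) > 0]
  }
  structure(sets, descriptions = descriptions, universe = universe,
            class = c("gene_set_collection", "list"))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d\n", length(x),
              if (length(x)) min(lengths(x)) else 0L,
              if (length(x)) max(lengths(x)) else 0L))
  invisible(x)
}

#' Read / write a 2-column pathway edge list
#'
#' Tab-delimited, one undirected edge per line.
#' @param path path to the edge list.
#' @return data.frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list must have 2 columns", call. = FALSE)
  stats::setNames(df[, 1:2], c("from", "to"))
}

#' @rdname read_edge_list
#' @param edges data.frame with columns `from`, `to`.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a PPI score table
#'
#' Three tab-delimited columns: protein1, protein2, combined_score.
#' @param ppi data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param path output path.
#' @export
write_ppi_table <- function(ppi, path) {
  utils::write.table(ppi[, c("protein1", "protein2", "combined_score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
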