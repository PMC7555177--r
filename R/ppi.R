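# Protein-protein interaction graphs: read 3-column score tables with a
# high-confidence threshold, annotate pathway membership, and detect
# functional modules by edge-clustering-coefficient (ECC) agglomeration.

#' Read a PPI score table into a thresholded graph
#'
#' Expects three tab-delimited columns: protein1, protein2,
#' combined_score. Scores in the integer 1-1000 dialect are rescaled to
#' [0, 1] automatically (detected by a maximum above 1). Edges below
#' `threshold` are dropped (kept iff `score >= threshold`), duplicate
#' pairs collapsed keeping the maximum score, and self-loops removed.
#'
#' @param path path to the table (header row optional).
#' @param threshold minimum combined score (default 0.700, the
#'   conventional high-confidence cutoff).
#' @return an `igraph` graph with edge attribute `combined_score`.
#' @export
read_ppi_table <- function(path, threshold = 0.700) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (suppressWarnings(is.na(as.numeric(parts[[1]][3]))) ||
      length(parts[[1]]) < 3) {
    start <- 2L  # header row
  }
  if (start > length(parts)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  rows <- parts[start:length(parts)]
  bad <- which(lengths(rows) < 3)
  if (length(bad) > 0) {
    stop("PPI table format error: fewer than 3 columns at line ",
         bad[1] + start - 1L, " of ", path, call. = FALSE)
  }
  p1 <- vapply(rows, `[[`, "", 1L)
  p2 <- vapply(rows, `[[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
  if (anyNA(sc)) {
    stop("PPI table format error: non-numeric score at line ",
         which(is.na(sc))[1] + start - 1L, " of ", path, call. = FALSE)
  }
  ppi_graph(data.frame(protein1 = p1, protein2 = p2, combined_score = sc,
                       stringsAsFactors = FALSE), threshold = threshold)
}

#' @rdname read_ppi_table
#' @param ppi data.frame with columns `protein1`, `protein2`,
#'   `combined_score` (as produced by [generate_ppi_table()]).
#' @export
ppi_graph <- function(ppi, threshold = 0.700) {
  sc <- ppi$combined_score
  if (length(sc) > 0 && max(sc) > 1) sc <- sc / 1000  # 1-1000 dialect
  if (length(sc) > 0 && (min(sc) < 0 || max(sc) > 1)) {
    stop("PPI table format error: scores outside [0, 1]", call. = FALSE)
  }
  keep <- sc >= threshold & ppi$protein1 != ppi$protein2
  df <- data.frame(from = ppi$protein1[keep], to = ppi$protein2[keep],
                   combined_score = sc[keep], stringsAsFactors = FALSE)
  # collapse duplicate pairs (either orientation), keeping the max score
  key <- ifelse(df$from < df$to, paste(df$from, df$to, sep = "\r"),
                paste(df$to, df$from, sep = "\r"))
  ord <- order(key, -df$combined_score)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Annotate pathway membership of PPI nodes
#'
#' Labels every node by its membership in the two pathways of interest:
#' `"seed"` (listed seed proteins; wins over any other label), `"both"`,
#' `"signaling_only"`, `"metabolism_only"`, or `"unannotated"`.
#'
#' @param graph an `igraph` PPI graph.
#' @param signaling_set,metabolism_set character vectors of member genes.
#' @param seed_proteins optional character vector of seed proteins.
#' @return the graph with a `membership` vertex attribute.
#' @export
annotate_membership <- function(graph, signaling_set, metabolism_set,
                                seed_proteins = character(0)) {
  nodes <- igraph::V(graph)$name
  in_sig <- nodes %in% signaling_set
  in_met <- nodes %in% metabolism_set
  lab <- rep("unannotated", length(nodes))
  lab[in_sig & !in_met] <- "signaling_only"
  lab[!in_sig & in_met] <- "metabolism_only"
  lab[in_sig & in_met] <- "both"
  lab[nodes %in% seed_proteins] <- "seed"
  igraph::set_vertex_attr(graph, "membership", value = lab)
}

#' Edge clustering coefficient
#'
#' `ECC(u, v) = (z + 1) / min(deg(u) - 1, deg(v) - 1)` where `z` is the
#' number of triangles containing the edge (common neighbors of `u` and
#' `v`). For pendant edges, where the denominator vanishes, ECC is defined
#' as 0.
#'
#' @param graph an `igraph` graph.
#' @param edge character vector of the two endpoint names.
#' @return the edge's ECC (numeric scalar).
#' @export
edge_clustering_coefficient <- function(graph, edge) {
  u <- edge[1]; v <- edge[2]
  if (!igraph::are_adjacent(graph, u, v)) {
    stop("edge (", u, ", ", v, ") not present in graph", call. = FALSE)
  }
  nu <- igraph::neighbors(graph, u)$name
  nv <- igraph::neighbors(graph, v)$name
  z <- length(intersect(nu, nv))
  denom <- min(length(nu) - 1, length(nv) - 1)
  if (denom <= 0) return(0)
  (z + 1) / denom
}

# ECC for every edge at once; returns data.frame from,to,ecc,combined_score
ecc_table <- function(graph) {
  el <- igraph::as_edgelist(graph)
  if (nrow(el) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      ecc = numeric(0), combined_score = numeric(0)))
  }
  nbrs <- lapply(igraph::as_adj_list(graph), function(x) x$name)
  deg <- lengths(nbrs)
  ecc <- vapply(seq_len(nrow(el)), function(i) {
    u <- el[i, 1]; v <- el[i, 2]
    denom <- min(deg[[u]] - 1, deg[[v]] - 1)
    if (denom <= 0) return(0)
    (length(intersect(nbrs[[u]], nbrs[[v]])) + 1) / denom
  }, numeric(1))
  score <- igraph::edge_attr(graph, "combined_score")
  if (is.null(score)) score <- rep(NA_real_, nrow(el))
  data.frame(from = el[, 1], to = el[, 2], ecc = ecc,
             combined_score = score, stringsAsFactors = FALSE)
}

#' Functional module detection by ECC agglomeration
#'
#' Agglomerative module detection in the spirit of edge-clustering-
#' coefficient algorithms: edges are sorted by descending ECC (ties broken
#' by higher combined score, then lexicographic endpoints) and endpoint
#' modules merged via union-find whenever the edge's ECC is at least
#' `ecc_threshold`. Modules smaller than `min_module_size` are reported as
#' unassigned. The tie-breaking is total, so the partition does not depend
#' on input edge order.
#'
#' @param graph an `igraph` PPI graph (edge attribute `combined_score`
#'   used for tie-breaking when present).
#' @param ecc_threshold minimum ECC for a merge (default 1).
#' @param min_module_size smallest reported module (default 3).
#' @return list with `modules` (named list of node vectors, largest
#'   first), `membership` (named vector, NA for unassigned nodes) and
#'   `unassigned` (character vector).
#' @export
fag_ec_modules <- function(graph, ecc_threshold = 1, min_module_size = 3) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  et <- ecc_table(graph)
  if (nrow(et) > 0) {
    a <- pmin(et$from, et$to)
    b <- pmax(et$from, et$to)
    sc <- ifelse(is.na(et$combined_score), 0, et$combined_score)
    ord <- order(-et$ecc, -sc, a, b)
    et <- et[ord, , drop = FALSE]
    idx <- stats::setNames(seq_len(n), nodes)
    for (i in seq_len(nrow(et))) {
      if (et$ecc[i] < ecc_threshold) break
      ru <- find(idx[[et$from[i]]])
      rv <- find(idx[[et$to[i]]])
      if (ru != rv) parent[rv] <- ru
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(nodes, roots)
  sizes <- lengths(groups)
  big <- groups[sizes >= min_module_size]
  big <- big[order(-lengths(big),
                   vapply(big, function(g) sort(g)[1], ""))]
  names(big) <- if (length(big)) paste0("module", seq_along(big)) else
    character(0)
  unassigned <- sort(unlist(groups[sizes < min_module_size],
                            use.names = FALSE))
  membership <- stats::setNames(rep(NA_character_, n), nodes)
  for (m in names(big)) membership[big[[m]]] <- m
  list(modules = big, membership = membership,
       unassigned = as.character(unassigned))
}

#' Export a graph as GraphML
#'
#' @param graph an `igraph` graph (node/edge attributes are preserved).
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
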