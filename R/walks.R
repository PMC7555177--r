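# Gene-guided random walks on a pathway-to-pathway network. Walkers pick
# destinations in proportion to per-pathway guidance mass (counts of guide
# genes annotated to each pathway) and traverse one shortest path per
# destination, with periodic restarts; every node entered is counted as a
# visit and every edge traversal consumes one step of the budget. The
# topology-only walk uses identical mechanics with uniform destinations
# and is the null against which the per-pathway odds ratio is computed.

#' Walk configuration
#'
#' @param n_walkers number of independent walkers (default 6).
#' @param n_steps edge-traversal budget per walker (default 10000).
#' @param restart_every restart period (default 50): the walker teleports
#'   to a freshly sampled start every `restart_every` destination
#'   selections (`restart_unit = "destinations"`) or edge steps
#'   (`restart_unit = "steps"`).
#' @param restart_unit `"destinations"` (default) or `"steps"`.
#' @param seed integer seed; walks are reproducible under it.
#' @return list of class `walk_config`.
#' @export
walk_config <- function(n_walkers = 6, n_steps = 10000, restart_every = 50,
                        restart_unit = c("destinations", "steps"),
                        seed = 1) {
  restart_unit <- match.arg(restart_unit)
  stopifnot(n_walkers >= 1, n_steps >= 1, restart_every >= 1)
  structure(list(n_walkers = as.integer(n_walkers),
                 n_steps = as.integer(n_steps),
                 restart_every = as.integer(restart_every),
                 restart_unit = restart_unit, seed = as.integer(seed)),
            class = "walk_config")
}

#' Guidance mass per pathway from a guide-gene list
#'
#' @param guide_genes character vector of guide genes (e.g. consistently
#'   differentially expressed members of the pathways of interest).
#' @param collection a [gene_set_collection()].
#' @param pseudocount added to every pathway's count (default 0: pathways
#'   holding no guide genes are never sampled as destinations, though they
#'   are still visited en route).
#' @return named non-negative numeric vector, one entry per pathway.
#' @export
guide_scores <- function(guide_genes, collection, pseudocount = 0) {
  mass <- vapply(collection, function(members) {
    length(intersect(guide_genes, members))
  }, numeric(1)) + pseudocount
  if (sum(mass) <= 0) {
    stop("guidance error: no guide gene maps to any pathway",
         call. = FALSE)
  }
  mass
}

# shared engine for guided and topology-only walks; dest_mass is a named
# non-negative vector over (a superset of) the network's vertices
run_walk <- function(network, dest_mass, config) {
  comp <- igraph::components(network)
  main <- which.max(comp$csize)
  keep <- igraph::V(network)$name[comp$membership == main]
  g <- igraph::induced_subgraph(network, keep)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  mass <- dest_mass[nodes]
  mass[is.na(mass)] <- 0
  if (sum(mass) <= 0) {
    stop("guidance error: all guidance mass lies outside the walked ",
         "component", call. = FALSE)
  }
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  D <- igraph::distances(g)
  visits <- integer(n)
  etrav <- matrix(0L, n, n)
  by_steps <- config$restart_unit == "steps"
  withr::with_seed(config$seed, {
    for (w in seq_len(config$n_walkers)) {
      budget <- config$n_steps
      cur <- sample.int(n, 1, prob = mass)
      visits[cur] <- visits[cur] + 1L
      since_restart <- 0L
      while (budget > 0) {
        if (since_restart >= config$restart_every) {
          cur <- sample.int(n, 1, prob = mass)
          visits[cur] <- visits[cur] + 1L
          since_restart <- 0L
        }
        dest <- sample.int(n, 1, prob = mass)
        if (!by_steps) since_restart <- since_restart + 1L
        if (dest == cur) {
          # staying at the destination consumes one step; without this a
          # walker whose guidance mass sits entirely on its current node
          # would never spend its budget
          visits[cur] <- visits[cur] + 1L
          budget <- budget - 1L
          if (by_steps) since_restart <- since_restart + 1L
          next
        }
        drow <- D[, dest]
        while (cur != dest && budget > 0) {
          nb <- adj[[cur]]
          cand <- nb[drow[nb] == drow[cur] - 1]
          nxt <- if (length(cand) == 1) cand else
            cand[sample.int(length(cand), 1)]
          etrav[cur, nxt] <- etrav[cur, nxt] + 1L
          cur <- nxt
          visits[cur] <- visits[cur] + 1L
          budget <- budget - 1L
          if (by_steps) {
            since_restart <- since_restart + 1L
            if (since_restart >= config$restart_every && cur != dest) {
              break
            }
          }
        }
      }
    }
  })
  ew <- etrav + t(etrav)
  dimnames(ew) <- list(nodes, nodes)
  structure(list(visits = stats::setNames(visits, nodes),
                 total = sum(visits), n = n,
                 edge_traversals = ew, config = config,
                 dropped_nodes = setdiff(igraph::V(network)$name, nodes)),
            class = "walk_counts")
}

#' @export
print.walk_counts <- function(x, ...) {
  cat(sprintf("<walk_counts> %d pathways, %d recorded visits\n", x$n,
              x$total))
  top <- sort(x$visits, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  most visited:",
      paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Gene-guided random walk
#'
#' Destinations (and starts/restarts) are sampled proportionally to the
#' guidance mass; the walker follows one shortest path per destination,
#' breaking ties among equal-length shortest paths uniformly at random by
#' choosing among distance-decreasing neighbors at each node. Walks are
#' restricted to the network's largest connected component (dropped
#' isolates are recorded in the result).
#'
#' @param network an `igraph` pathway-to-pathway network with named
#'   vertices.
#' @param guides named guidance-mass vector from [guide_scores()].
#' @param config a [walk_config()].
#' @return a `walk_counts` object: per-pathway visit frequencies `visits`,
#'   their exact sum `total`, the symmetric `edge_traversals` count
#'   matrix, and bookkeeping.
#' @export
guided_walk <- function(network, guides, config = walk_config()) {
  run_walk(network, guides, config)
}

#' Topology-only random walk
#'
#' Identical mechanics to [guided_walk()] with destinations, starts and
#' restarts sampled uniformly over the walked component's nodes: the null
#' that isolates what visit frequency the network topology alone produces.
#'
#' @inheritParams guided_walk
#' @return a `walk_counts` object.
#' @export
topology_walk <- function(network, config = walk_config()) {
  mass <- stats::setNames(rep(1, igraph::vcount(network)),
                          igraph::V(network)$name)
  run_walk(network, mass, config)
}

#' Per-pathway odds ratio of guided versus topology-only walks
#'
#' With visiting probabilities `P_i = F_i / F_t` for each run, the odds
#' ratio is `OR_i = [P_iG / (1 - P_iG)] / [P_iT / (1 - P_iT)]`. Pathways
#' never visited by the topology run have undefined odds and are flagged
#' `unscorable` (OR = NA) rather than scored.
#'
#' @param guided `walk_counts` from [guided_walk()].
#' @param topo `walk_counts` from [topology_walk()] on the same network.
#' @return data.frame sorted by descending OR: `pathway_id`, `F_guided`,
#'   `P_guided`, `F_topo`, `P_topo`, `OR`, `or_gt_1`, `unscorable`.
#' @export
odds_ratio <- function(guided, topo) {
  if (!identical(sort(names(guided$visits)), sort(names(topo$visits)))) {
    stop("guided and topology walk counts cover different node sets",
         call. = FALSE)
  }
  ids <- names(guided$visits)
  fg <- guided$visits[ids]
  ft <- topo$visits[ids]
  pg <- fg / guided$total
  pt <- ft / topo$total
  unscorable <- pt == 0 | pt == 1 | pg == 1
  or <- ifelse(unscorable, NA_real_,
               (pg / (1 - pg)) / (pt / (1 - pt)))
  out <- data.frame(pathway_id = ids, F_guided = as.integer(fg),
                    P_guided = unname(pg), F_topo = as.integer(ft),
                    P_topo = unname(pt), OR = unname(or),
                    or_gt_1 = !is.na(or) & or > 1,
                    unscorable = unname(unscorable),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-ifelse(is.na(out$OR), -Inf, out$OR), out$pathway_id), ,
      drop = FALSE]
}

#' Louvain clustering of pathways weighted by walk traffic
#'
#' Runs Louvain modularity optimization on the walked component with edge
#' weights equal to the guided walk's edge-traversal counts plus one
#' (smoothing, so untraversed edges still connect).
#'
#' @param network the pathway network the walk ran on.
#' @param guided `walk_counts` from [guided_walk()].
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed making the partition deterministic.
#' @return data.frame `pathway_id`, `cluster`; modularity in attribute
#'   `modularity`.
#' @export
cluster_pathways <- function(network, guided, resolution = 1, seed = 1) {
  keep <- names(guided$visits)
  g <- igraph::induced_subgraph(network, keep)
  el <- igraph::as_edgelist(g)
  w <- guided$edge_traversals[cbind(el[, 1], el[, 2])] + 1
  comm <- withr::with_seed(seed, {
    igraph::cluster_louvain(g, weights = w, resolution = resolution)
  })
  out <- data.frame(pathway_id = igraph::V(g)$name,
                    cluster = as.integer(igraph::membership(comm)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "modularity") <- igraph::modularity(comm)
  out
}
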