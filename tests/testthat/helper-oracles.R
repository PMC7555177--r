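# Independent reference routines used as oracles; deliberately written
# with base-R primitives, not with the package's own code paths.

# gene-wise Welch-free two-sample pooled t-test p-values
oracle_t_test <- function(values, groups) {
  aff <- names(groups)[groups == "affected"]
  ctl <- names(groups)[groups == "control"]
  apply(values, 1, function(x) {
    stats::t.test(x[aff], x[ctl], var.equal = TRUE)$p.value
  })
}

# classical pooled two-sample t statistic per gene
oracle_pooled_t <- function(values, groups) {
  aff <- names(groups)[groups == "affected"]
  ctl <- names(groups)[groups == "control"]
  na <- length(aff); nc <- length(ctl)
  apply(values, 1, function(x) {
    a <- x[aff]; b <- x[ctl]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nc - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nc))
  })
}

# quantile normalization by explicit sort-and-average with tie averaging
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    # average the reference values a tied block spans
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    out[, j] <- (lo + hi) / 2
  }
  out
}

# unweighted KS running-sum statistic from hit positions, from scratch
oracle_gsea_stat <- function(positions, N) {
  k <- length(positions)
  inc <- rep(-sqrt(k / (N - k)), N)
  inc[positions] <- sqrt((N - k) / k)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# exact triangle count z for an edge by exhaustive common-neighbor scan
# over an edge-list representation
oracle_ecc <- function(edges, u, v) {
  nb <- function(x) {
    unique(c(edges[edges[, 1] == x, 2], edges[edges[, 2] == x, 1]))
  }
  nu <- nb(u); nv <- nb(v)
  z <- length(intersect(nu, nv))
  denom <- min(length(nu) - 1, length(nv) - 1)
  if (denom <= 0) 0 else (z + 1) / denom
}

# brute-force re-evaluation of the guided/topology odds ratio from raw
# count vectors
oracle_odds_ratio <- function(fg, ft) {
  pg <- fg / sum(fg)
  pt <- ft / sum(ft)
  (pg / (1 - pg)) / (pt / (1 - pt))
}

# wrap raw visit counts as a walk_counts object
make_walk_counts <- function(visits) {
  structure(list(visits = visits, total = sum(visits),
                 n = length(visits), edge_traversals = NULL),
            class = "walk_counts")
}
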