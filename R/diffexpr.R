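# Per-gene two-group differential expression: ordinary least squares on the
# affected-vs-control contrast, empirical-Bayes moderation of the residual
# variances (scaled inverse-chi-square prior, moment estimation via
# trigamma inversion), then the probe-level filtering cascade.

#' Fit the per-gene affected-vs-control linear model
#'
#' For each gene (row) computes the affected-minus-control mean difference
#' on the log2 scale and the pooled residual variance with
#' `n_affected + n_control - 2` degrees of freedom. Carrier samples are
#' excluded from the design.
#'
#' @param dataset a harmonized [expression_dataset()] (log2 scale).
#' @param gene_map optional named character vector probe ID -> gene symbol;
#'   when absent, row IDs are treated as gene symbols.
#' @return data.frame of class `gene_fits` with columns `probe`, `gene`,
#'   `log2FC`, `residual_var`, `df_residual`, and attributes `n_affected`,
#'   `n_control`.
#' @export
fit_linear_model <- function(dataset, gene_map = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  aff <- names(dataset$groups)[dataset$groups == "affected"]
  ctl <- names(dataset$groups)[dataset$groups == "control"]
  if (length(aff) < 2 || length(ctl) < 2) {
    stop("design error: need >= 2 affected and >= 2 control samples ",
         sprintf("(got %d affected, %d control)", length(aff), length(ctl)),
         call. = FALSE)
  }
  a <- dataset$values[, aff, drop = FALSE]
  c_ <- dataset$values[, ctl, drop = FALSE]
  ma <- rowMeans(a)
  mc <- rowMeans(c_)
  ss <- rowSums((a - ma)^2) + rowSums((c_ - mc)^2)
  df <- length(aff) + length(ctl) - 2L
  probes <- rownames(dataset$values)
  genes <- if (is.null(gene_map)) probes else {
    g <- unname(gene_map[probes])
    ifelse(is.na(g), probes, g)
  }
  out <- data.frame(probe = probes, gene = genes,
                    log2FC = unname(ma - mc),
                    residual_var = unname(ss / df),
                    df_residual = df,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_affected") <- length(aff)
  attr(out, "n_control") <- length(ctl)
  class(out) <- c("gene_fits", "data.frame")
  out
}

# Solve trigamma(y) = x by the monotone Newton iteration on 1/trigamma
# (converges for all x > 0); tolerance on the relative step.
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50L) {
  stopifnot(length(x) == 1, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < tol * y) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Assumes the gene-wise residual variances follow a scaled
#' inverse-chi-square prior with `d0` degrees of freedom and location
#' `s0_sq`, estimated by matching the first two moments of the log residual
#' variances (closed form via trigamma inversion). Posterior variances are
#' the usual weighted combination `(d0*s0_sq + df*s2) / (d0 + df)`.
#'
#' @param fits a `gene_fits` table from [fit_linear_model()].
#' @param d0,s0_sq optional fixed prior degrees of freedom / prior variance
#'   overriding the moment estimates (`d0 = 0` disables moderation,
#'   `d0 = Inf` shrinks every variance to `s0_sq`).
#' @return list with elements `d0`, `s0_sq` and numeric vector `post_var`
#'   (one posterior variance per row of `fits`).
#' @export
moderate_variances <- function(fits, d0 = NULL, s0_sq = NULL) {
  s2 <- fits$residual_var
  df <- fits$df_residual
  pos <- s2 > 0 & df > 0
  if (!any(pos)) {
    stop("degenerate-variance error: all residual variances are zero",
         call. = FALSE)
  }
  if (is.null(d0) || is.null(s0_sq)) {
    if (sum(pos) < 50) {
      warning("fewer than 50 genes with positive residual variance; ",
              "prior moment estimates will be unstable")
    }
    e <- log(s2[pos]) - digamma(df[pos] / 2) + log(df[pos] / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df[pos] / 2))
    if (is.na(evar) || evar <= 0) {
      est_d0 <- Inf
      est_s0 <- exp(emean)
    } else {
      est_d0 <- 2 * trigamma_inverse(evar)
      est_s0 <- exp(emean + digamma(est_d0 / 2) - log(est_d0 / 2))
    }
    if (is.null(d0)) d0 <- est_d0
    if (is.null(s0_sq)) s0_sq <- est_s0
  }
  post_var <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  list(d0 = d0, s0_sq = s0_sq, post_var = post_var)
}

#' Moderated t differential expression table
#'
#' Combines [fit_linear_model()] output with moderated variances into the
#' per-probe DEG table: moderated t, two-sided p-value on `d0 + df` degrees
#' of freedom, and Benjamini-Hochberg adjusted p (reported alongside; the
#' filtering cascade uses the raw p-value).
#'
#' @param fits a `gene_fits` table.
#' @param moderation optional result of [moderate_variances()]; computed
#'   from `fits` when omitted.
#' @return data.frame of class `deg_table` with columns `probe`, `gene`,
#'   `log2FC`, `t`, `p_value`, `adj_p`; attributes `d0`, `s0_sq`.
#' @export
moderated_t_table <- function(fits, moderation = NULL) {
  if (is.null(moderation)) moderation <- moderate_variances(fits)
  na <- attr(fits, "n_affected")
  nc <- attr(fits, "n_control")
  se <- sqrt(moderation$post_var * (1 / na + 1 / nc))
  tstat <- fits$log2FC / se
  df_total <- moderation$d0 + fits$df_residual
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(probe = fits$probe, gene = fits$gene,
                    log2FC = fits$log2FC, t = tstat, p_value = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- moderation$d0
  attr(out, "s0_sq") <- moderation$s0_sq
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Full differential expression for one dataset
#'
#' Convenience wrapper: [fit_linear_model()] then [moderated_t_table()].
#'
#' @inheritParams fit_linear_model
#' @inheritParams moderate_variances
#' @return a `deg_table` (see [moderated_t_table()]).
#' @export
diff_expression <- function(dataset, gene_map = NULL, d0 = NULL,
                            s0_sq = NULL) {
  fits <- fit_linear_model(dataset, gene_map = gene_map)
  moderated_t_table(fits, moderate_variances(fits, d0 = d0, s0_sq = s0_sq))
}
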