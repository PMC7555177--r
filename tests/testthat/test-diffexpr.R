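test_that("linear model fit matches hand arithmetic and an OLS oracle", {
  m <- rbind(g1 = c(2, 2, 1, 1), g2 = c(3, 3, 3, 3))
  colnames(m) <- paste0("s", 1:4)
  grp <- stats::setNames(rep(c("affected", "control"), each = 2),
                         colnames(m))
  fits <- fit_linear_model(expression_dataset(m, grp))
  expect_equal(fits$log2FC, c(1, 0))
  expect_equal(fits$residual_var, c(0, 0))
  expect_equal(fits$df_residual, c(2L, 2L))

  set.seed(41)
  r <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  grp6 <- stats::setNames(rep(c("affected", "control"), each = 3),
                          colnames(r))
  fits6 <- fit_linear_model(expression_dataset(r, grp6))
  for (i in 1:10) {
    ols <- stats::lm(r[i, ] ~ I(grp6 == "affected"))
    expect_equal(fits6$log2FC[i], unname(coef(ols)[2]), tolerance = 1e-10)
    expect_equal(fits6$residual_var[i],
                 sum(residuals(ols)^2) / ols$df.residual,
                 tolerance = 1e-10)
  }
  expect_error(
    fit_linear_model(expression_dataset(
      r[, 1:3], stats::setNames(c("affected", "control", "control"),
                                colnames(r)[1:3]))),
    "design error")
})

test_that("moderation limits behave as shrinkage theory dictates", {
  set.seed(13)
  m <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
  grp <- stats::setNames(rep(c("affected", "control"), each = 4),
                         colnames(m))
  fits <- fit_linear_model(expression_dataset(m, grp))
  # d0 = 0: moderated t equals the classical pooled t
  tab0 <- moderated_t_table(fits, moderate_variances(fits, d0 = 0,
                                                     s0_sq = 1))
  expect_equal(tab0$t, unname(oracle_pooled_t(m, grp)),
               tolerance = 1e-10)
  # d0 = Inf: every posterior variance collapses to s0_sq
  modInf <- moderate_variances(fits, d0 = Inf, s0_sq = 0.7)
  expect_equal(modInf$post_var, rep(0.7, 100))
  # monotonicity: larger d0 pulls posterior variances toward s0_sq
  m1 <- moderate_variances(fits, d0 = 2, s0_sq = 1)$post_var
  m2 <- moderate_variances(fits, d0 = 20, s0_sq = 1)$post_var
  expect_true(all(abs(m2 - 1) <= abs(m1 - 1) + 1e-12))
  # degenerate input
  fits$residual_var[] <- 0
  expect_error(moderate_variances(fits), "degenerate-variance")
})

test_that("prior moment estimation recovers a planted inverse-chi-square
           prior and agrees with the established moderated-t oracle", {
  set.seed(9)
  n <- 2000; na <- 4; nc <- 4
  sd_g <- sqrt(0.05 * 4 / stats::rchisq(n, 4))
  m <- matrix(stats::rnorm(n * (na + nc), sd = rep(sd_g, na + nc)),
              nrow = n, dimnames = list(sprintf("g%04d", 1:n),
                                        paste0("s", 1:8)))
  grp <- stats::setNames(rep(c("affected", "control"), c(na, nc)),
                         colnames(m))
  deg <- diff_expression(expression_dataset(m, grp))
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, grp == "affected")))
  expect_equal(attr(deg, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(deg, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(deg$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(deg$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("type-I error of the moderated test is nominal on null data", {
  rates <- vapply(1:3, function(s) {
    ds <- generate_cohort(cohort_spec(n_datasets = 1, n_genes = 4000,
                                      n_affected = 5, n_control = 5,
                                      seed = 100 + s))$datasets[[1]]
    mean(diff_expression(ds)$p_value < 0.05)
  }, numeric(1))
  expect_true(all(abs(rates - 0.05) < 0.015))
})

test_that("filtering cascade applies the multi-sign and lowest-p rules", {
  tab <- make_deg_table(
    gene = c("A", "A", "B", "B", "C"),
    log2FC = c(1.2, -0.8, 1.2, 0.5, 0.4),
    p_value = c(0.01, 0.03, 0.01, 0.04, 0.2))
  out <- filter_degs(tab)
  expect_false("A" %in% out$gene)   # opposite-sign probes
  expect_false("C" %in% out$gene)   # fails p cutoff
  expect_equal(out$log2FC[out$gene == "B"], 1.2)  # lowest p wins
  expect_equal(out$p_value[out$gene == "B"], 0.01)
  expect_equal(nrow(filter_degs(make_deg_table(character(0), numeric(0),
                                               numeric(0)))), 0)
})

test_that("coding filter drops excluded biotypes and prefixes", {
  tab <- make_deg_table(
    gene = c("LOC100128", "GBA2", "RPL13A", "RP11-34A2.1", "FLJ10986",
             "MIR21"),
    log2FC = rep(1, 6), p_value = rep(0.01, 6))
  lit <- coding_filter(tab)
  expect_setequal(lit$gene, c("GBA2", "MIR21"))
  clone <- coding_filter(tab, rp_prefix_mode = "clone_only")
  expect_setequal(clone$gene, c("GBA2", "RPL13A", "MIR21"))
  bt <- c(MIR21 = "miRNA", GBA2 = "protein_coding")
  with_bt <- coding_filter(tab, biotype = bt)
  expect_setequal(with_bt$gene, "GBA2")
})

test_that("top selection applies the strict fold-change cutoff and cap", {
  tab <- make_deg_table(
    gene = c("X1", "X2", "X3", "X4"),
    log2FC = c(0.585, 0.9, -1.4, 0.6),
    p_value = c(0.001, 0.01, 0.02, 0.03))
  expect_identical(select_top(tab), c("X3", "X2", "X4"))  # 0.585 excluded
  expect_identical(select_top(tab, top_n = 2), c("X3", "X2"))
  big <- make_deg_table(sprintf("G%03d", 1:600),
                        log2FC = seq(0.6, 6, length.out = 600),
                        p_value = rep(0.01, 600))
  expect_length(select_top(big), 500)
})

test_that("DEG overlap counts match exhaustive set enumeration", {
  t1 <- make_deg_table(c("a", "b", "c", "d", "e"),
                       c(1, 1, -1, 1, -1), rep(0.01, 5))
  t2 <- make_deg_table(c("b", "c", "d", "f", "g"),
                       c(1, 1, -1, 1, -1), rep(0.01, 5))
  t3 <- make_deg_table(c("b", "d", "x", "y", "z"),
                       c(1, 1, 1, -1, 1), rep(0.01, 5))
  ov <- deg_overlap(list(d1 = t1, d2 = t2, d3 = t3))
  # hand enumeration: d1&d2 share b,c,d; signs agree for b (+,+) and
  # nothing else (c: -/+, d: +/-)
  pw <- ov$pairwise
  expect_equal(pw$n_any_sign[pw$dataset_a == "d1" & pw$dataset_b == "d2"],
               3)
  expect_equal(pw$n_same_sign[pw$dataset_a == "d1" & pw$dataset_b == "d2"],
               1)
  # three-way: b, d present everywhere; same sign only for b
  expect_equal(unname(ov$kway["n_any_sign"]), 2)
  expect_equal(unname(ov$kway["n_same_sign"]), 1)
  # identical tables: k-way equals table size; disjoint tables: zero
  same <- deg_overlap(list(t1, t1))
  expect_equal(unname(same$kway["n_any_sign"]), 5)
  expect_equal(unname(same$kway["n_same_sign"]), 5)
  t4 <- make_deg_table(c("q", "r"), c(1, 1), c(0.01, 0.01))
  expect_equal(unname(deg_overlap(list(t1, t4))$kway["n_any_sign"]), 0)
})
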