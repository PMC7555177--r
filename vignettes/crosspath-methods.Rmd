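---
title: "Cross-dataset pathway analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-dataset pathway analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspath)
```

crosspath implements a multi-stage inference chain for case/control
transcriptomic compendia: heterogeneous expression matrices are harmonized
onto a common scale, differential expression is assessed per dataset with an
empirical-Bayes moderated t, and the gene-level results are aggregated into
pathway-level evidence three ways — enrichment statistics, a pathway
expression score, and a guided random walk on a pathway-to-pathway network
scored against a topology-only null. A synthetic-cohort generator with known
ground truth closes the loop so every stage is testable without external
data. This vignette records the statistical models, the tunable parameters
and their defaults, and the places where the design was genuinely open.

## Harmonization

Microarray datasets arrive in mixed conventions: some matrices are linear
intensities, some are already log2, and background-subtracted exports can
contain negative values. `harmonize()` applies one fixed pipeline so that
all downstream fold changes are comparable:

1. values flagged log2 are reverse-transformed (`2^x`);
2. `positive_shift()` — if the matrix minimum `m` is at or below zero,
   every entry is increased by `-m + 0.01`, making the new minimum exactly
   0.01 (the 0.01 clears zeros before the log);
3. `quantile_normalize()` — every column is forced onto the common
   reference distribution given by the row-wise mean of sorted columns
   (the limma `normalizeQuantiles` routine; ties receive the average of
   the reference values they span, the established microarray convention);
4. log2 transform.

Two choices here were not fully determined by convention. A minimum of
exactly zero receives the same shift as a negative minimum — zeros must be
cleared either way and the rule stays continuous in `m`. Missing cells are
imputed as the row median before normalization and the count is reported on
the returned object; imputation keeps the column multisets aligned without
inventing rank structure.

`detect_log_scale()` flags a matrix as log2 when its maximum is at most 30
(boundary inclusive). Log2 intensities rarely exceed ~20 while linear
scanner output reaches the thousands, so the threshold sits in a wide empty
region; it is advisory and overridable per dataset.

## Differential expression

For each gene the model is a two-group comparison on the log2 scale:
`log2FC = mean(affected) − mean(control)` with pooled residual variance
`s²` on `df = n_a + n_c − 2` degrees of freedom. Carrier samples are
retained in the data object but never enter the design. Both groups must
contribute at least two samples so that `df ≥ 2`.

Variance moderation assumes the gene-wise true variances follow a scaled
inverse-chi-square prior with `d0` degrees of freedom and location `s0²`.
The posterior variance is the standard weighted combination
`(d0·s0² + df·s²)/(d0 + df)`, and the moderated t uses it with `d0 + df`
degrees of freedom. The prior parameters are estimated by matching the
first two moments of `log s²`: with
`e = log s² − ψ(df/2) + log(df/2)`, the excess variance
`var(e) − ψ′(df/2)` equals `ψ′(d0/2)`, inverted by a damped Newton
iteration on the trigamma function (relative tolerance 1e-8, at most 50
iterations; in practice it converges in a handful). When the excess
variance is non-positive the prior is degenerate (`d0 = ∞`) and every
posterior variance collapses to `s0²`. The estimator is authored in this
package; the test suite cross-checks it against the independent
limma implementation of the same moment estimators (agreement to 1e-6 on
`d0` and `s0²`, 1e-8 on t and p) and verifies that `d0 = 0` reproduces the
classical pooled t to 1e-10.

Two-sided p-values are used throughout; Benjamini–Hochberg adjusted values
are computed and reported alongside but the filtering cascade operates on
the raw p-value — multi-dataset microarray cohorts of this size rarely
leave usable gene lists after FDR control, and the cross-dataset
consistency requirement downstream supplies the error control instead.

## The filtering cascade

`filter_degs()` applies, in order: the raw p cutoff (default 0.05,
strict `<`); removal of any gene whose surviving probes disagree in fold-
change sign (an irreconcilable measurement); and lowest-p deduplication of
same-sign probes (ties broken by larger |log2FC|, then probe ID, so the
result is order-independent). The multi-sign check deliberately runs after
the p cutoff: a non-significant opposite-sign probe does not disqualify a
gene.

`coding_filter()` drops non-coding and uncharacterized annotations: the
biotype exclusion list (ncRNA, miRNA, miscRNA, snRNA, snoRNA,
uncharacterized) plus the symbol prefixes LOC, FLJ and RP. The literal RP
rule also removes ribosomal-protein symbols (RPL/RPS); because the more
common intent of such a rule is RP11-style clone identifiers, the mode is
switchable (`rp_prefix_mode = "clone_only"` restricts it to
`RP<digits>-`). The literal rule is the default.

`select_top()` keeps genes with `|log2FC|` strictly above 0.585
(≈1.5-fold) and caps the list at the top 500 by absolute fold change, with
ties resolved by ascending p then gene ID so the selection is total.

## Enrichment

`over_representation()` is the one-sided hypergeometric tail
`P(overlap ≥ observed)` against the measured universe (the genes scorable
on the platform after the coding filter — the fairest background when the
query was drawn from the same platform). The combined score is
`−ln(p) · z` with `z` the standardized deviation of the observed overlap
from its hypergeometric mean: significance times effect size, in the
convention popularized by web enrichment services. Exactness of the tail
is verified against exhaustive enumeration on small universes.

`unweighted_gsea()` is the unweighted Kolmogorov–Smirnov running sum:
`+√((N−k)/k)` at set members, `−√(k/(N−k))` elsewhere, statistic = the
signed extreme deviation (the increments sum to zero over the full list).
Significance is by permutation of hit positions — exhaustive over all
`C(N,k)` placements when that count is at most 50,000, otherwise by 1,000
seeded random placements with the +1 correction so p is never exactly 0.

`consistent_terms()` keeps a term selected (p < 0.05) in at least
`⌈min_fraction · n_datasets⌉` datasets; the default fraction is 1/3 and
the ceiling makes "at least one-third" exact for any dataset count.

## Pathway expression score

For a pathway with `n_total` measured member genes and a member DEG table:

* `rateFC` = (over-expressed member DEGs)/`n_total` ∈ [0, 1];
* `normMeanFC` = weighted mean of the normalized histogram of member
  log2FC values — values clipped to ±`range_limit`, binned into `n_bins`
  equal-width bins, frequencies normalized to sum 1, then the mean of bin
  centers. Defaults `n_bins = 20`, `range_limit = 4` log2 units: 0.4-wide
  bins resolve the 0.585 effect-size scale while ±4 (16-fold) covers all
  but pathological microarray fold changes; the estimator converges to the
  clipped arithmetic mean as `n_bins → ∞`.
* `combinedFC = rateFC + clip((normMeanFC + range_limit)/(2·range_limit), 0, 1)`.

The combining function is this package's own construction — the published
quantity fixes the two ingredients, the [0, 2] range and the reading
(above 1: majority over-expression; below 1: overall under-expression) but
not the formula. The affine-clipped form is the simplest function meeting
that contract: both terms move monotonically with their ingredient, a
balanced pathway (half its genes up, zero mean shift) scores exactly 1,
and the extremes 0 and 2 are attained. Scores from any other combining
rule with the same contract would order pathways similarly but are not
numerically comparable; this is the central reimplementation caveat of the
package. The denominator `n_total` counts pathway members inside the
measured universe rather than the full annotation so that scores are
comparable across platforms.

`consistency_scores()` flags a gene as consistent when its majority
direction recurs in at least `max(2, ⌈min_fraction · n⌉)` datasets — the
floor of 2 operationalizes "recurs across datasets", and conflicting signs
elsewhere reduce nothing but the minority count (a gene can be robustly up
in one tissue and down in another; both facts are reported, per tissue).

## Guided walks and the odds ratio

The walk operates on an undirected pathway-to-pathway network (edges =
functional connections; in the synthetic generator, shared membership of
at least `min_shared` genes). Guidance mass per pathway is the count of
guide genes annotated to it, with pseudocount 0: pathways holding no guide
genes are never sampled as destinations but are freely visited en route.
Each of 6 walkers, with a 10,000-step budget, repeatedly samples a
destination proportionally to guidance mass and follows one shortest path
toward it; every edge traversal consumes one step and every node entered
counts one visit. Ties among equal-length shortest paths are broken
uniformly at random by sampling among distance-decreasing neighbors at
each node, which samples paths without enumerating them. Every 50
destination selections the walker teleports to a freshly guide-sampled
node ("restart"; an alternative reading — every 50 edge steps — is
available via `restart_unit`). A destination equal to the current node
consumes one step in place; without that rule a walker whose entire
guidance mass sits on its current pathway would never spend its budget,
and with it the degenerate single-node network correctly accumulates the
whole budget on its one node. The topology-only walk is the identical
mechanics with uniform destination mass — under uniform guidance the two
are the same code path, which the tests assert exactly.

Walks are restricted to the largest connected component (isolates are
recorded), and with `F_i` visits of pathway `i` out of `F_t` total, the
per-pathway visiting probability is `P_i = F_i/F_t` and the guided-versus-
topology odds ratio is

    OR_i = [P_iG/(1 − P_iG)] / [P_iT/(1 − P_iT)]

Pathways the topology run never visits have undefined odds and are flagged
unscorable rather than scored. OR > 1 marks pathways visited more than
their topological centrality alone explains. Two independent topology runs
at the standard budget give OR within [0.8, 1.25] for ≥95% of pathways on
a 100-node network — the sampling noise floor against which OR > 1 calls
should be read. Louvain clustering (resolution 1, seeded) runs on the
walked component with edge weights equal to guided traversal counts plus
one (smoothing keeps untraversed edges connected).

The step semantics (one edge = one step) make visit counts comparable
across path lengths. The guidance model — destination sampling by raw
membership counts — is a declared simplification: the original tool family
drives walkers through a separate gene-network layer whose mechanics are
not recoverable from the published description; membership-count guidance
preserves the interface (guide genes in, visit frequencies and OR out) and
the null comparison, but not necessarily the original tool's exact
rankings.

## PPI modules

PPI tables (protein1, protein2, combined_score; the 1–1000 integer dialect
is auto-rescaled by its maximum) are thresholded at 0.700 — the
conventional high-confidence cutoff, kept iff `score ≥ 0.700` — with
duplicate pairs collapsed to their maximum score. The edge clustering
coefficient is `ECC(u,v) = (z + 1)/min(deg(u) − 1, deg(v) − 1)` with `z`
the number of triangles on the edge; pendant edges, where the denominator
vanishes, are assigned ECC 0 (they can never evidence a module). Module
detection is agglomerative: edges sorted by descending ECC (ties by higher
score, then lexicographic endpoints — a total order, so the partition is
independent of input edge order) and endpoint modules merged by union–find
while ECC ≥ `ecc_threshold` (default 1, the value separating triangle-
supported edges from bridges in sparse graphs); modules below
`min_module_size` (default 3) are reported unassigned. This is the
simplest agglomerative form of ECC-based module detection; in-/out-degree
λ-module refinements of the published algorithm family are out of scope.

## The synthetic generator

`generate_cohort()` emulates the structure of a multi-tissue microarray
compendium: per-gene baseline log2 expression drawn once, uniform on
4–12 (the dynamic range typical of log2 intensities), shared across the
cohort's datasets; i.i.d. Gaussian noise per gene per sample on the log2
scale (default sd 0.5, a mid-range per-gene variability for arrays);
additive mean shifts on affected samples for designated gene sets; and a
`consistent_fraction` controlling in how many datasets each perturbation
is active (`⌈fraction × n⌉`, seeded), which exercises the one-third
consistency rule directly. Export dialects reproduce the real-world mess:
`linear` (2^x), and `linear_with_negatives` (linear shifted so the minimum
is negative, as in background-subtracted arrays) — harmonizing the linear
export reproduces the log2 cohort exactly, and the negative dialect
reproduces its rank structure. Optional probe duplication emits two probes
per gene with independent noise and, for a configurable fraction of
perturbed genes, opposite injected signs, exercising the multi-sign
filter.

What the generator does not model: probe-level background and saturation,
batch effects, correlated gene-gene noise, and RNA-seq count distributions.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under a clean additive-Gaussian regime, not
robustness to array artifacts — on real data the harmonization and
consistency layers carry that burden and their behavior there is untested
here.

Standard problem sizes in the test suite were chosen to exercise each
property at the smallest scale where it is statistically sharp: 10,000
genes for type-I calibration (±0.01 at α = 0.05), the 1,000-gene /
50-perturbed / 10v10 cohort for power (a two-sample t at δ = 1, σ = 0.5
has essentially full power there, so ≥80% recovery is a loose floor), a
100-pathway network at the standard 6 × 10,000 walk budget for OR
calibration, and exhaustive enumeration wherever the space is small enough
(sign patterns to n = 6, GSEA placements at N = 10, k = 3, graphs to 12
nodes).

## Known limitations

* The pathway combining formula and the walk guidance model are this
  package's own constructions within published contracts (above); numeric
  values are not interchangeable with the original services'.
* Single-dataset tissues cannot satisfy the 2-dataset consistency floor;
  the pipeline falls back to that dataset's target-pathway DEGs as walk
  guides and records it.
* The moderated model covers the two-group design only — no paired or
  multi-factor designs, no array weights.
* Enrichment assumes the universe is the measured platform; supplying a
  whole-genome universe will inflate significance.
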