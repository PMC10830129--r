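---
title: "Methods: scoring disease-affected cell types from single-cell expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring disease-affected cell types from single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellpredict)
```

# The problem

Mendelian diseases are annotated with causal genes and affected tissues, but a
tissue is a mixture of cell types, and the pathology usually emerges from a
subset of them. `cellpredict` infers which cell types of an affected tissue a
disease is likely to affect, using only single-cell RNA-seq of the healthy
tissue and the disease's gene set. The premise is that disease genes tend to be
*preferentially expressed* in the cell types whose dysfunction produces the
phenotype.

# The scoring model

## Preferential expression

Per tissue, raw UMI counts are normalized cell-wise,
$v = \log\!\left(1 + \text{count} \cdot s / \text{cell total}\right)$ with
scale $s = 10^4$ — the standard library-size log-normalization of single-cell
toolkits. Genes are kept when at least one cell type expresses them
($v \ge 0.05$) in at least 10% of its cells; both boundaries are inclusive.
Normalized values are averaged per cell type into $e_{gc}$, and — because
sparse profiles make low-expression averages unstable — only genes whose
average in some cell type *strictly* exceeds the median over all entries of
the average matrix are retained.

Preferential expression is the per-gene Z-score across the $K$ cell types of
one tissue:

$$P_{gc} = \frac{e_{gc} - \overline{e_{g\cdot}}}{\mathrm{SD}(e_{g\cdot})}.$$

The SD uses the population convention (`ddof = 0`), the common default of
scientific Z-score routines; `ddof = 1` is available and recorded in the
output. Genes with zero cross-type SD carry no signal and are dropped with a
report. Every retained row has mean 0 and unit SD by construction, which the
test suite asserts to $10^{-10}$.

A useful consequence of standardizing across $K$ values: a gene elevated in a
single cell type and flat elsewhere cannot exceed $Z = \sqrt{K-1}$. This bound
drives several simulator defaults (below).

## The PrEDiCT score and its permutation null

The score of disease $D$ in cell type $c$ is the median preferential
expression of its genes:
$\mathrm{PrEDiCT}_D(c) = \mathrm{median}(P_{g_1 c}, \ldots, P_{g_n c})$, with
the usual mean-of-middle-pair convention for even $n$. Catalog genes missing
from the retained universe are dropped (reported via `n_genes_used` vs
`n_genes_catalog`); an empty intersection yields an `NA` row flagged
`no_expressed_genes`.

Significance comes from a gene-set permutation null: per repeat, *one* random
set of $n$ genes is sampled without replacement from the tissue's retained
universe and scored in *all* cell types, preserving the cross-cell-type
correlation of the null. With 1000 repeats (the default), the p-value in $c$
is the plain fraction of random scores at least as high as the observed one.
The add-one estimator $(k+1)/(R+1)$ is available behind a flag but off by
default, so reported p-values match the plain-fraction definition. On small
universes an exhaustive mode enumerates all $\binom{m}{n}$ sets; the test
suite checks sampled p-values against that enumeration.

P-values are Benjamini–Hochberg adjusted *within each disease and tissue*. For
a disease annotated to several tissues the adjustment is per tissue: the
cell-type hypotheses of different tissues answer different questions and
pooling them would couple unrelated comparisons. An association is **likely**
when the score reaches 1 (inclusive) and the FDR is below 0.1 (strict).

Functional subsets (ligands vs receptors, oncogenes vs tumor suppressors) are
scored by `score_gene_subsets()`, which reruns the whole pipeline per subset
with the null sized to the subset — a disease whose ligand and receptor genes
act in different cell types can be resolved where the joint median dilutes
both signals.

# Cross-tissue and cross-species cell-type matching

Markers of a cell type are genes with $P_{gc} \ge 2$ (inclusive). For
cross-species comparisons, markers are first mapped through an ortholog table;
many-to-many orthology is resolved by taking the union of targets, which is
deterministic and maximizes recall. For a comparison between two tissues (or
species), the Jaccard index is computed for *all* cell-type pairs, and a pair
matches when its Jaccard index is at least 0.05 *and* reaches the 90th
percentile (inclusive) of the comparison's pooled pairwise distribution. The
percentile is taken over the full pairwise matrix rather than per row: the
per-row variant makes matching asymmetric in the two sides, while the pooled
variant keeps the match table symmetric up to transposition (asserted in the
tests). `rematch_excluding_genes()` reruns matching without a gene set of
interest (typically disease genes) and reports the concordance of the match
set, guarding against circularity between scoring and matching.

# Validation statistics

* **Literature co-appearance** (`coappearance_test()`): per tissue, the record
  universe is the union of all record IDs of that tissue's entities; each
  disease–cell-type pair forms a 2×2 table of record membership tested
  one-sided for over-representation. Pairs with fewer than three joint records
  are not tested (an alternative reading — dropping the disease entirely — is
  behind a flag), cell types never mentioned with any disease are excluded,
  and p-values are Bonferroni-corrected within the tissue with support called
  at adjusted $p < 0.001$. Fisher's exact test is the default; a chi-squared
  variant is available by flag, but the exact test is preferred because the
  tables are typically sparse. The decision statistic is the exact-test
  p-value itself.
* **Enrichment** (`enrichment_fisher()`): one-sided Fisher test of the
  overlap between likely and gold-standard associations within the evaluated
  universe.
* **Error-rate curves** (`error_rates_vs_threshold()`): holding the score
  cutoff fixed, the FDR threshold is swept; FPR is the fraction of non-gold
  associations predicted (standard confusion-matrix denominator: all evaluated
  associations not in the gold set) and FNR the fraction of gold associations
  missed. Monotonicity (FPR non-decreasing, FNR non-increasing) is asserted on
  every run of the test suite.
* **Matched-score correlation** (`matched_score_correlation()`): Spearman
  correlation of a disease's scores across cell-type pairs, stratified by the
  matched flag; strata with fewer than three pairs report `NA`.
* **Cross-tissue agreement** (`matching_permutation_test()`): per disease,
  success means any likely cell type in the reference tissue matches any
  likely cell type in the test tissue; the null redraws the reference-tissue
  likely set uniformly at the same size (the test-side redraw is available by
  flag), and the p-value is the fraction of permutations reaching the observed
  success count.

# Susceptibility summaries

Susceptibility of a cell type is the fraction of its tissue's diseases that
likely affect it; prevalence is the fraction of the tissue's cells it
contributes. Class-level comparisons use one-way ANOVA across cell classes,
two-sided Mann–Whitney tests of each *prevalent* class (by default, more than
15 cell types across at least 4 tissues, recomputed from the input rather than
hard-coded) against all other cell types with BH adjustment, and the Pearson
correlation of susceptibility with prevalence. Degenerate inputs (constant
susceptibility, fully tied groups) return the conventional no-evidence values
($F = 0$, $p = 1$) rather than NaN.

# The synthetic-data generator

Real atlas-scale inputs are impractical for routine verification, so the
package ships a generator that plants known structure and exposes it as
ground truth:

* **Counts** are negative binomial (`base_mean = 0.3`, `dispersion = 2`),
  overdispersed like UMI data, with a lognormal per-gene baseline
  (meanlog −2, sdlog 1.2). The baseline spread was chosen once so that the
  expressed-gene filter retains roughly half the genes — sparse enough that
  the filter genuinely participates, dense enough that tissues keep a usable
  universe.
* **Markers**: each cell type owns `markers_per_type = 25` genes elevated
  `marker_fold = 8`-fold, disjoint across the cell types of a tissue.
* **Disease effects**: each disease is assigned a tissue, an affected cell
  type, and 3–10 genes elevated there. The elevation is parameterized on the
  Z scale (`effect_z = 3`) because that is the scale the scoring operates on.
  Since $Z \le \sqrt{K-1}$, the default uses $K = 12$ cell types per tissue
  (bound ≈ 3.32). The generator self-calibrates: it draws the baseline
  counts, estimates the cross-type noise SD $s$ of normalized mean expression
  from its own background genes, inverts
  $z = d\,(K-1)/K \big/ \sqrt{s^2 + d^2 (K-1)/K^2}$ for the required shift
  $d$ on the normalized scale, and maps that back to a count mean by
  numerically inverting the expected normalized value of a negative-binomial
  gene. Across seeds this lands planted genes at a realized Z close to the
  target (median ≈ 3.1 at defaults).
* **Species pairs** share the planted design under re-drawn counts and
  distinct gene identifiers linked by a one-to-one ortholog map;
  `ortholog_noise` scrambles a fraction of the map.
* **Literature**: record membership is Bernoulli per entity
  (`base_rate = 0.05`); planted pairs receive extra jointly-assigned records
  with probability $\text{base\_rate}^2(\text{signal}-1)$, so `signal = 1` is
  exactly the independent null.

What the generator does *not* emulate: batch and sample effects, doublets,
ambient RNA, correlated gene modules, or imbalanced cell-type abundances.
Passing the recovery suites therefore demonstrates the correctness and
calibration of the machinery under the stated generative model, not
performance on real atlases.

# Problem sizes and numerical choices

The test and acceptance runs use the generator defaults — 2 tissues (1 for
species pairs), 12 cell types × 40 cells, 1500 genes, 20 diseases, 1000
permutation repeats — over 20 seeds for recovery checks; these sizes are the
package's chosen verification scale. Other conventions, fixed once:

* outputs are sorted lexicographically (radix order) so repeated runs are
  byte-identical;
* the above-median retention uses strict `>` ("exceeded"), so a constant
  average matrix retains nothing;
* the retention median is computed over all expressed genes, before any rows
  are dropped for zero SD;
* empty-vs-empty Jaccard is 0 (an empty overlap cannot support a match);
* all thresholds on scores, markers and Jaccard are inclusive (`>=`), the FDR
  cutoff is strict (`<`);
* a single seed set at entry drives each stochastic routine, with diseases
  processed in sorted order; the seed is recorded in the result attributes.

# Limitations

The score treats all disease genes equally: no weighting by association
strength, expression reliability, or cell-level covariates (approaches in the
style of per-cell disease scoring are out of scope). The pipeline consumes a
prepared disease catalog and cell-type annotations; ontology traversal,
clustering and annotation quality are upstream concerns. Tissues with few
cell types bound the attainable Z, compressing scores toward the threshold;
with a single cell type preferential expression is undefined and the pipeline
refuses to proceed.

# A short end-to-end example

```{r example, eval = FALSE}
sim <- generate_dataset(sim_config(seed = 1))
pref <- preferential_expression_by_tissue(sim$dataset)
res <- predict_diseases(pref, sim$truth$catalog, reps = 1000, seed = 2)
glance(res)
autoplot(res, tissue = "tissue01")
```
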