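---
title: "Methods: cross-species co-expression prioritization of glial genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species co-expression prioritization of glial genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`gliafunnel` implements a desk-scale, fully testable version of a
cross-species systems-biology workflow for prioritizing glial genes in
progressive supranuclear palsy (PSP) and related tauopathies. The workflow
combines five evidence layers:

1. **Two-cohort bulk differential expression.** Per-gene ordinary least
   squares of log2 expression on diagnosis (and, within cases, quantitative
   tau-pathology scores), adjusted for sex, age at death, RIN and flowcell,
   optionally also for estimated cell-type proportions; the two cohorts are
   combined by inverse-variance meta-analysis with Higgins–Thompson
   I² model switching and Benjamini–Hochberg FDR control.
2. **A consensus weighted co-expression network** built from biweight
   midcorrelations, the signed soft-threshold adjacency
   \(a_{ij} = ((1+\mathrm{bicor}_{ij})/2)^{12}\), per-cohort topological
   overlap matrices (TOM), and their quantile-scaled component-wise minimum;
   modules come from average-linkage clustering of \(1-\Omega\) with a
   tree-shape cut, then eigengene-based merging and membership-based
   reassignment.
3. **Single-nucleus validation**: QC, library-size normalization,
   PC embedding with light-weight per-sample integration, shared-nearest-
   neighbor Louvain clustering, marker-based cell-type annotation, and both
   hurdle-model (nucleus-level) and pseudobulk negative-binomial
   (sample-level) differential expression.
4. **Tauopathy-mouse validation**: negative-binomial GLMs of genotype
   (rTg4510 vs non-transgenic) per age group, adjusted for sex and RIN; a
   human hit validates if any ortholog is significant in either age group
   with the same direction.
5. **A fly modifier screen**: RNAi lines scored on a semi-quantitative
   −4..4 eye-degeneration scale; scores below −1.5 define top suppressors.

The layers compose into a nested evidence funnel: disease-associated glial
module DEGs → hub genes (module membership > 0.7) → concordant single-nucleus
DEGs in the module's cell type → mouse-validated genes → genes with fly
orthologs and available RNAi → top suppressors.

Because the human, mouse, and raw fly data behind the original study are
access-restricted, the package ships a synthetic-data generator that plants
known ground truth in every layer. All quantitative claims in the test suite
and in `scripts/acceptance.R` are statements about recovery of that planted
truth, not about the original cohorts.

# The synthetic-data generator

`simulation_config()` fixes the study design; every generator is a pure
function of its seed. The reference configuration is two cohorts of 100
samples (half cases), 2,000 genes with six planted modules (two neuronal,
one each oligodendrocyte, astrocyte, endothelial, microglial; 900 module
genes in total), a 2,000-nucleus single-nucleus dataset over 10 samples, a
two-age-group mouse study with 5 animals per genotype per group, and
ortholog/screen tables.

**Expression model.** Each module gene's log2 mean is
`base + log2(p_t(s)) + loading * h_m(s) + dx + pathology + batch + noise`:

* `log2(p_t(s))` ties module genes to the sample's planted proportion of the
  module's cell type (Dirichlet across five brain cell types), which makes
  the same genes usable as deconvolution markers;
* `h_m` is a shared per-module Gaussian factor (SD 1 by default). It is
  residualized against diagnosis within each cohort so that the planted
  case–control effect is exactly the configured value rather than the value
  plus a chance factor–diagnosis correlation; without this, module-level
  confounding of order \(\pm 0.2\) log2 units leaks into every member gene's
  estimate and no per-gene method could be expected to recover the planted
  effect unbiasedly;
* planted diagnosis effects of ±1 log2 unit are applied to a configurable
  fraction (default 0.5) of each module's genes, signed by cell type (glial
  up, neuronal and oligodendrocyte down). Planting only a fraction keeps the
  differentially expressed mass a minority of the transcriptome, which is
  what makes median-based normalization well-posed (below);
* counts are Poisson draws of the exponentiated means (log-normal-Poisson),
  so they are over-dispersed and normalization has real work; library sizes,
  flowcell offsets, and per-sample GC/length trends are planted on top.

**Planted targets** are genes guaranteed, by construction, to span every
evidence layer: they are strong bulk DEGs (1.5× the module effect, so a
chance switch to the noisier random-effects model cannot mask them), high
loading and low noise (hubs), well expressed in the single-nucleus and
mouse data, always concordant in the mouse arm, always have fly orthologs
with available RNAi, and always receive screen scores below −1.5.
Non-target screened genes receive scores centred at 0 and truncated above
−1.5; this separation is the ground-truth contract that makes exact funnel
recovery a testable property. A small set of QC violations is also planted
(a sex-swapped sample and a composition-outlier sample per bulk cohort;
low-UMI and high-mitochondrial nuclei).

**What the generator does not emulate:** read-level artifacts, isoform
structure, doublets, ambient RNA, non-additive batch effects, and
correlated per-sample effects in the single-nucleus arm beyond additive
offsets. Passing tests therefore demonstrate correctness of the statistical
machinery on data satisfying its assumptions, not robustness to every
pathology of real tissue data.

# Numerical and design choices

**Normalization.** Full conditional-quantile normalization is deliberately
not reimplemented. Sequencing depth is estimated by median-of-ratios size
factors against a per-gene median-CPM reference profile: the reference is
scale-invariant in every sample, so rescaling one sample's counts changes
exactly that sample's factor (an exact invariance the tests assert), and
the median over genes is unbiased as long as differentially expressed genes
are a minority — total-count CPM, by contrast, showed a composition bias of
~0.15 log2 units on the planted effects. GC and length effects are removed
per sample by windowed-median trends (20 equal-occupancy windows, linear
interpolation), re-centred so the median adjustment per sample is zero.

**Batch correction.** The default is moment-matching location–scale
correction (per gene, each batch is standardized and rescaled to the pooled
mean and variance). This form is exactly idempotent — a property the suite
asserts at 1e−6 — whereas empirical-Bayes shrinkage is only approximately
so; the parametric EB variant (ComBat-style shrinkage of batch means and
variances across genes) is available as `method = "eb"` and is
cross-checked against `sva::ComBat` in the tests.

**Sample QC.** Outliers are samples whose PC1 or PC2 score lies outside
mean ± 3 SD; sex is estimated from the median expression of chromosome-Y
genes, thresholded at the midpoint of the two cluster centres of its
bimodal distribution, and compared with the recorded sex. Samples with
missing sex are reported as unevaluable, never silently dropped.

**Deconvolution.** Marker-based: a cell type's linear-scale marker mean is
proportional to its proportion; the per-type proportionality constants are
solved from the sum-to-one constraint by projected-gradient non-negative
least squares (tolerance 1e−8), and each sample is projected onto the
simplex. Proportions are identifiable only when they vary across samples;
a cohort with constant composition carries no information about the
per-type scales.

**Meta-analysis.** Fixed-effect weights \(1/se^2\); \(Q\), \(I^2 =
\max(0, (Q - df)/Q)\) with \(df = 1\) for two studies, truncated at zero;
the fixed-effect result is reported when \(I^2 < 0.3\) (strict comparison),
otherwise DerSimonian–Laird with \(\tau^2 = \max(0, (Q - df)/(\sum w -
\sum w^2 / \sum w))\). P-values use the normal approximation on
\(\beta/se\). With only two studies, \(I^2\) is extremely noisy; genuinely
identical effects are pushed to the random-effects model in a non-trivial
fraction of genes, which mainly costs power. This is a property of the
published rule, not of the implementation; the tests cross-check both
branches against `metafor`.

**Network.** The biweight midcorrelation uses median centering and the
conventional 9-MAD outlier cutoff, with a Pearson fallback for zero-MAD
genes (recorded, never silent). The soft power is fixed at 12; a raw
correlation is not a valid adjacency, so the standard signed transform is
applied. The TOM denominator is \(\min(k_i, k_j) + 1 - a_{ij}\). Consensus:
each non-reference TOM is power-rescaled so its 0.95 off-diagonal quantile
matches the reference (study 1), then the element-wise minimum is taken.
Module detection is the simple tree-shape variant of dynamic tree cut:
average-linkage clustering of \(1 - \Omega\), cut at 0.99 of the *maximum*
merge height. Background genes join the dendrogram only in its topmost
merges, so cutting just below the top isolates the dense branches; a cut
placed relative to the height *range* instead lands above the background
region and absorbs noise genes into modules (module recovery degraded from
ARI ≈ 0.99 to ≈ 0.37 in development, which is why the maximum-height
parametrization was chosen). Both the cut height and the minimum module
size (30) are configuration parameters.

**Merging and reassignment.** Closest-pair merging of modules with
eigengene bicor > 0.8 (ties broken by module id), then moving genes with
negative own-module membership to the background, then pulling background
genes with maximum membership > 0.5 into the argmax module. These steps are
iterated to a fixed point (at most 10 rounds) rather than applied once:
recomputing eigengenes after the moves can re-trigger either rule, and the
fixed point is what makes the operation idempotent — a second call changes
no labels, which the acceptance suite asserts on 20 random networks.

**Preservation.** A simplified two-statistic permutation Z: the observed
statistic is the mean of (a) the correlation of intramodular connectivity
between studies and (b) the mean intramodular adjacency in study 2, and the
null is random gene sets of the same size (100 permutations, seeded). Note
that between two faithful replicate cohorts, statistic (a) is high for
*any* gene set (the whole network replicates), so discrimination between
modules and random sets is carried by the density statistic (b); with
genuinely identical inputs strong modules score Z > 10. This is a
deliberate simplification of the full multi-statistic Z-summary.

**Single-nucleus arm.** QC removes nuclei below 1,000 UMIs or above the
98th percentile, below 500 detected genes or above the 98th percentile, or
above 10% mitochondrial fraction, then genes detected in fewer than 6
nuclei, then re-checks the nucleus bounds once (a fixed point in two
passes). Normalization scales each nucleus to the median library and
applies `log1p`; the top 500 dispersion-ranked genes feed a 30-PC embedding
whose component signs are fixed by the largest-loading convention.
Integration is per-sample centering of PC scores — a deliberately simple
substitute for published harmonization algorithms that removes additive
per-sample offsets (the planted batch structure) and is switchable off.
Clustering builds a 20-nearest-neighbor graph with shared-neighbor Jaccard
weights (pruned below 1/15) and runs seeded Louvain at resolution 0.4
(0.3 for subclustering), labelling clusters CL0, CL1, … by decreasing size.

**Hurdle model.** Per gene detected in ≥ 20% of the cluster's nuclei
(the Methods-stated threshold; the 10% variant is reachable through the
configuration): a logistic model of detection and a Gaussian model of
log-normalized expression among detected nuclei, both on diagnosis + sex +
age; the diagnosis term is tested by the summed 2-df likelihood-ratio
chi-square. Complete separation triggers a ridge-penalized logistic refit
(flagged per gene). Fold changes are differences of mean log-normalized
expression over all nuclei. Under the null generator the test's size is
close to nominal (≈ 0.05–0.06 at α = 0.05); under sample-level batch
variation nucleus-level tests are anticonservative (pseudo-replication),
which is exactly why the pseudobulk route is also provided.

**Pseudobulk / mouse NB GLMs.** Counts are summed per sample, then fitted
with a negative-binomial GLM with log link, size-factor normalization,
trended dispersion moderation and a Wald test — delegated to DESeq2 with
independent filtering and outlier replacement disabled so results are a
deterministic function of the inputs. A planted ×2 effect on genes that
dominate the library is partially absorbed into the normalization
(composition effect); with markers at moderate elevation the planted unit
log2 fold change is recovered with bias well under 0.15.

**Funnel.** Modules enter the funnel by data-driven annotation: a module is
glial if its genes are significantly enriched (Bonferroni hypergeometric)
in a glial marker set, and its required single-nucleus direction is the
sign of its eigengene–diagnosis association. Cluster eligibility is by
annotated cell type, never by hard-coded cluster ids, so synthetic runs
resolve the same rule as real ones. Hub status uses the gene's own final
module's membership. One-to-many mouse orthologs validate if any ortholog
is concordant. Lethal fly outcomes are categorical and never enter the
top-suppressor rule.

# Problem sizes and determinism

The test suite and acceptance script run everything at the reference scale
above (2,000 genes, 100+100 samples, ~2,000 nuclei) or smaller; a full
synthetic pipeline run takes about a minute on one CPU. Every stochastic
step — generators, Louvain, permutation nulls, control-gene sampling — is
seeded from the configuration, and the suite asserts byte-identical results
for repeated runs.

# Known limitations

* The two-study I² switch is noisy by construction; borderline genes can
  lose significance through chance heterogeneity.
* Nucleus-level differential expression ignores within-sample correlation.
* The simplified preservation statistic is conservative between replicate
  cohorts (see above).
* Deconvolution assumes mutually exclusive markers and varying composition.
* The tree-shape cut is a static-height approximation of dynamic tree cut;
  deeply nested module structure would need the hybrid variant.
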