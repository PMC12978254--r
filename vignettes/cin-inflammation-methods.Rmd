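---
title: "Methods: from micronuclei to inflamed, myeloid-skewed tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from micronuclei to inflamed, myeloid-skewed tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The scientific setting

Chromosomally unstable tumors continuously mis-segregate chromosomes.
Lagging chromatin forms micronuclei (MN); ruptured micronuclear envelopes
expose DNA to the cytosolic sensor cGAS, so cGAS-decorated MN are an
in-situ, per-tumor readout of *ongoing* CIN. Chronic cGAS–STING engagement
rewires tumors toward chemokine-driven myeloid recruitment rather than
acute antiviral immunity. The package's pipelines quantify each link of
that chain: scoring MN in stained sections, asking which cells co-locate
with MN-dense regions, which genes scale with MN burden, which induced
genes need cGAS, how unstable the karyotypes actually are, and how CIN and
myeloid skew stratify patient survival.

## MN scoring

Candidate cGAS foci from segmented images are filtered by area within
[0.25, 7.5] µm² — bounds are inclusive, since the source protocol states a
range without open/closed notation — and by a per-tumor intensity
threshold. The threshold is deliberately an explicit *input*: in practice
it is tuned per tumor against staining intensity, and no reproducible rule
for it exists. `otsu_threshold()` is provided as a labeled heuristic
(maximum between-class variance on the focus intensity histogram), not as
a replication of any tuning procedure. The score is
`100 * n_MN / n_tumor_cells`. Artifact-class cells (necrosis, debris) are
excluded from every denominator, and stromal foci never enter the
numerator. Marker intensities are divided per cell by the cell's inferred
autofluorescence before compartment averaging; cells with non-positive
autofluorescence are dropped with a warning rather than silently producing
infinities.

## Hotspot enrichment

The MN point pattern is smoothed with `MASS::kde2d` on a regular grid
(default 100 × 100; the analysis drivers use 40–60 for speed). Bandwidth
defaults to the quartile-robust normal-reference rule per axis, expressed
as the kernel standard deviation, with a 2 µm floor so that degenerate
(coincident) inputs stay finite — the floor triggers a warning. The tissue
mask is the convex hull of the cell centroids dilated by one grid cell; a
real section has holes and ragged borders, but the mask only has to keep
percentile ranks from being diluted by empty field corners.

Density percentiles are integer bins: a masked node with rank *r* of *N*
(max ties) gets `ceiling(100 * r / N)`, so constant surfaces collapse to
bin 100 and a strictly increasing surface over 100 nodes fills bins
1…100. Percentiles are computed over grid nodes, not over cell-assigned
densities; cells are then mapped to their *nearest* node (bilinear
interpolation was rejected so that an exact counting oracle exists — the
test suite recomputes every fold enrichment by brute-force nearest-node
counting and requires bitwise equality). Fold enrichment at threshold *t*
uses shares of all cells inside vs outside; a type with zero cells on
either side is excluded at that threshold, and tumors with ten or fewer MN
detections are excluded upstream.

Across a cohort, each (cell type, threshold) gets a two-sided one-sample
t-test of FE against 1, with medians and a 1.58·IQR/√n interval reported
alongside. Two caveats are documented deliberately. First, the 71
thresholds are heavily correlated and no multiplicity correction is
applied — the sweep is descriptive, matching how such curves are read.
Second, because the density surface is estimated from MN points emitted by
tumor cells, hotspots are mechanically slightly enriched for tumor cells
even under a null generator; immune-type FE is correspondingly biased a
few percent below 1, and the t-test of *immune* enrichment is mildly
anti-conservative (the acceptance script reports the null rejection rate
both for immune types and for all classes, and the tumor class itself is
not part of the immune-abundance question).

## Per-gene mixed models and the CIN-MN signature

Counts from the isogenic clone panel are filtered (total ≥ 50, nonzero in
≥ 4 samples) and normalized by median-of-ratios size factors followed by
log2(x + 1). This is a variance-stabilizing stand-in, not the exact VST
curve: the generators define true effects on the log2 scale, so slope
recovery — the property that is actually load-bearing — is cleanest on
that scale. The per-gene model is

```
expression ~ MN + (1 | clone) + (1 | batch)
```

fitted by REML, with the MN fixed effect's ANOVA F-test (Satterthwaite
degrees of freedom) giving the p-value. MN enters as the clone-level mean
burden. The random effects are *crossed*, not nested: with one RNA-seq
sample per clone per batch, a batch-within-clone intercept would have one
observation per level and is indistinguishable from the residual (lme4
refuses the fit), whereas experimental batches are shared sessions across
clones and carry exactly the between-batch correlation the model must
absorb. The generator draws batch effects per (gene, batch), shared across
clones, to match. If a mixed fit fails outright the gene falls back to OLS
and is flagged.

The CIN-MN signature restricts to positive slopes, ranks by ascending
p-value with ties broken by larger slope (a deterministic rule; the source
procedure does not state one), and takes the top 70. With the default
generator (2,000 genes, 10% CIN genes, slopes ±[0.5, 1.5]·0.08 log2 units
per MN%, clone/batch/residual SDs 0.15/0.10/0.25, NB dispersion 0.05) the
acceptance run measures slope recovery, uniformity of null-gene p-values,
and signature recall against truth.

## Single-sample GSEA and skew

`ssgsea_score()` ranks genes within each sample, walks the ranked list
accumulating the rank-weighted (exponent 0.25, the method's published
default) in-set CDF minus the unweighted out-set CDF, and sums the
difference. Scores are normalized by their range across samples, per set —
the method's standard normalization; with a single sample the
normalization is skipped. Scoring is invariant to monotone transforms of
expression and to gene order; signature genes absent from the matrix are
dropped with a warning. The myeloid:lymphoid skew is the plain difference
of the two signature scores, which keeps it on the same normalized scale
and symmetric around zero. Compartment signatures themselves follow the
exclusive-marker rule: a gene qualifies for a compartment only if
significantly up-regulated against a cluster outside the compartment and
never significantly up for any other compartment; the top 50 by best
adjusted p are kept.

## cGAS dependence

Differential expression for the 2×2 knockout design goes through DESeq2
(median-of-ratios size factors, NB GLM, Wald test, BH adjustment) — the
standard tool for exactly this step. Batch structure is handled by
*pairing* rather than pre-correction: per-batch log2 fold changes
(pseudocount 0.5 on normalized counts; the source is silent, and 0.5 keeps
low counts sane without distorting large ones) are compared between
genotypes by a two-sided paired t-test across batches, plus the
directional gate `mean lfc(proficient) > mean lfc(knockout)` that the
classification implies but never formalizes. A gene is dependent-induced
iff padj ≤ 0.01 with positive fold change in proficient cells *and* the
paired test at p ≤ 0.05 shows attenuated induction in the knockout.

A power ceiling is worth stating plainly: with three batches the paired
test has two degrees of freedom. At NB dispersion 0.05 the per-batch log2FC
difference between genotypes has standard deviation
√(4·0.05)/ln 2 ≈ 0.645, so even a fully abolished induction of 2 log2
units gives noncentrality ≈ 5.4 against a critical t of 4.30 — power
≈ 0.77 at best, before count-level shot noise. The classifier's
sensitivity under these conditions sits near 0.66 with a false-positive
rate around 10⁻³; the corresponding acceptance expectation of ≥ 0.9 is
not attainable under its own stated conditions and is left failing by
design, with the false-positive half passing. Consensus hits are the
intersection of dependent-induced calls across cell lines.

## Karyotype metrics

All three scores are exact arithmetic on the copy-number matrix: per-bin
|CN − expected| averaged with bin sizes as weights (per library, then
averaged per sample); the share of discordant cell pairs per bin
(equality-based — any CN difference counts), size-weighted per sample; and
adjacent same-chromosome CN changes per megabase. Expected ploidy is
configurable (X chromosome, whole-genome-doubled clones). Library QC keeps
cells whose mean reads per chromosome copy is ≥ 10, excluding zero-copy
bins; without read counts QC is skipped with a warning. Every score is
checked against independent loop-based oracles.

## Preranked GSEA

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum (weight = |metric|), computed in O(|set|) from the member positions;
the test suite checks it against a full running-sum oracle and against
fgsea's statistic. The null is gene-label permutation — the only null
available to preranked input — with NES = ES / mean(|null ES| of the same
sign), nominal p from the same-sign null tail (with an add-one
correction), and FDR q by the standard sign-stratified pooling of
normalized null and observed scores. Ties in the metric are broken by gene
name, so results are deterministic at a fixed seed. Sets intersecting the
ranked list in fewer than 3 genes are skipped; a set covering the whole
list degenerates to ES = 1 by convention. Pathway-group meta-enrichment
re-ranks the first-pass *gene sets* by NES (the natural summary of the
first pass; the source names no specific metric) and runs the same
preranked machinery over group membership.

## Cohort models and survival

Interaction and agreement models are ordinary least squares:
`Feature ~ MN × Response` over TRG 1–2 responders and 4–5 nonresponders
(TRG 3 excluded), `CIN score ~ CIN-MN + purity + leukocyte fraction`, and
`expression ~ CIN-MN × cGAS-STING + purity + leukocyte` with the
two-gate dependence classification (both main-effect and interaction p
≤ 0.05 with concordant signs).

Survival uses the survival package: product-limit curves, k-group and
pairwise log-rank tests, and Cox partial likelihood with Efron tie
handling, reporting the Wald interval and the log-rank p side by side. The
maximally selected rank statistic is implemented directly: candidate
cutpoints are the unique score values between the 10th and 90th
percentiles, the standardized two-group log-rank statistic is computed for
all cutpoints at once by vectorized risk-set counting (checked against
`survdiff` at every cutpoint), and the selection-adjusted p-value comes
from ≥ 1,000 permutations of the score labels rather than an asymptotic
improved-Bonferroni bound — exact analytic corrections vary between
implementations, while the permutation null is assumption-free at this
cohort size. Nested median stratification splits at the CIN-score median
and then at each half's own skew median; values exactly at a median go to
the "low" stratum, a fixed convention.

## What the generators emulate — and what they do not

The generators reproduce the *statistical structure* each analysis
assumes: spatially clustered MN with cell-type re-weighting inside
isotropic Gaussian hotspots (real tumors have irregular geometry; the
acceptance properties are parameter recovery, not tissue realism); Poisson
MN counts per tumor cell with a spatially varying rate (no model of MN
genesis); log-linear MN–expression scaling with Gaussian clone/batch
intercepts and NB counts; shared per-batch effects in the paired knockout
design; whole-chromosome plus segmental copy-number events at a Poisson
rate; and exponential survival with log-hazard linear in standardized CIN
score and skew, with independent exponential censoring. They do not
emulate segmentation error, spectral bleed-through, ambient RNA, doublets,
GC and mappability artifacts, subclonal structure, or non-proportional
hazards — so green tests demonstrate that the *pipelines* are correct and
calibrated under their stated models, not that those models exhaust real
data. Each generator takes one seed and restores the caller's RNG state.

## Problem sizes and determinism

The test suite and acceptance script size their simulations to run on one
CPU in a few minutes while leaving Monte-Carlo error well inside the
asserted tolerances: 20 tissues for oracle equivalence and 200 for null
calibration (40×40 grids, 600 tumor + 600 stromal cells each), the full
2,000-gene mixed-model configuration, ten 2,000-gene knockout replicates,
500 GSEA null simulations at 200 permutations, and 120 max-stat null
cohorts of 60 subjects at 250 permutations. All stochastic steps are
seeded; `scripts/acceptance.R --seed` drives every derived seed.

## Known limitations

- The per-tumor intensity threshold for MN detection has no principled
  estimator here; Otsu's rule is a labeled heuristic.
- The hotspot t-test inherits the ratio-statistic bias discussed above;
  log-scale or permutation alternatives would be calibrated but would no
  longer mirror the reference analysis.
- The dependence classifier's sensitivity is power-limited at three
  batches; more batches, not better code, is the remedy.
- ssGSEA normalization is per set across samples; cross-set score
  comparability relies on that convention being applied uniformly.
- The max-stat permutation p is exchangeable-null based; with strong
  covariate structure a stratified permutation would be needed.
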