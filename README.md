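# cinflam

Quantitative machinery for linking ongoing chromosomal instability (CIN) in
tumors — read out in situ as cGAS-positive micronuclei (MN) — to inflammatory
gene expression and myeloid-skewed tumor microenvironments.

Chromosomally unstable tumors such as esophageal adenocarcinoma continuously
mis-segregate chromosomes. Lagging chromosomes end up in micronuclei whose
envelopes rupture and expose DNA to the cytosolic sensor cGAS, chronically
stimulating cGAS–STING signaling and a chemokine program that recruits
myeloid cells. This package implements, as tested and reusable R functions,
the statistical pipeline needed to study that axis:

- **In-situ MN scoring** (`mn_scoring`): candidate cGAS foci from segmented
  multiplexed-immunofluorescence object tables are filtered by area
  (0.25–7.5 µm², inclusive) and a per-tumor intensity threshold; the score is
  `100 · n_MN / n_tumor cells` (cGAS⁺ MN per 100 tumor cells). Marker
  intensities are autofluorescence-normalized per cell and averaged per
  compartment.
- **Spatial hotspot enrichment** (`spatial_hotspots`): the MN point pattern
  is turned into a kernel density surface (product-Gaussian KDE,
  normal-reference bandwidth), quantized into 1% percentile bins, and for
  every threshold t ∈ {25, …, 95} the fold enrichment of cell type *c* in
  the hotspot H(t) = {nodes ≥ t-th percentile} is
  FE = [n(c, in)/n(·, in)] / [n(c, out)/n(·, out)], with a one-sample
  t-test of FE against 1 across tumors.
- **CIN-gene discovery** (`cin_association`): per gene, a linear mixed model
  `expression ~ MN + (1 | clone) + (1 | batch)` over an isogenic clone panel;
  the top 70 positive-slope genes by p-value form the CIN-MN signature.
  Signature scoring uses single-sample GSEA (rank-weighted CDF difference,
  exponent 0.25), and the myeloid:lymphoid skew is the difference of the two
  compartment signature scores.
- **cGAS dependence** (`cgas_dependence`): MPS1i-induced genes (DESeq2 Wald
  test, BH-adjusted p ≤ 0.01, log₂FC > 0 in cGAS-proficient cells) whose
  per-batch induction is significantly attenuated in cGAS-knockout cells
  (two-sided paired t-test across batches, p ≤ 0.05, paired by batch) are
  classified cGAS-dependent; consensus hits are intersected across lines.
- **Karyotype metrics** (`karyotype_metrics`): from binned single-cell
  copy-number matrices — bin-size-weighted aneuploidy |CN − expected|,
  pairwise between-cell heterogeneity, breakpoints per Mb, and a
  reads-per-copy library QC (≥ 10).
- **Pseudobulk + GSEA** (`pseudobulk_gsea`): per-compartment pseudobulk
  aggregation, per-gene Pearson correlation with tumor MN scores, and
  preranked GSEA (weighted Kolmogorov–Smirnov ES, gene-label permutation
  null, sign-stratified NES/FDR), including second-pass meta-enrichment of
  pathway groups.
- **Cohort models and survival** (`cohort_stats`): `Feature ~ MN × Response`
  interaction models (TRG 1–2 responders vs 4–5 nonresponders),
  `CIN score ~ CIN-MN + purity + leukocyte fraction` agreement models,
  `expression ~ CIN-MN × cGAS-STING` dependence classification,
  Kaplan–Meier/log-rank, Cox proportional hazards (Efron ties), maximally
  selected rank-statistic dichotomization with a permutation p-value, and
  nested median stratification into CIN-high/low × myeloid/lymphoid strata.

Every input the pipeline consumes can be simulated with known ground truth
by the `make_*` generators (`synthetic_data`), so all claims are tested as
parameter recovery, calibration, or closed-form agreement.

## Worked example

Score one simulated stained section and quantify macrophage enrichment in
its MN-dense regions:

```r
library(cinflam)

tis  <- make_tissue(tissue_sim_config(hotspot_multiplier = c(Macrophage = 3),
                                      seed = 7))
keep <- filter_mn_candidates(tis$foci, area_min = 0.25, area_max = 7.5)
compute_mn_score(keep, tis$cells, tumor_id = "tumor_07")
#>   tumor_id n_mn n_tumor_cells    score flagged
#> 1 tumor_07   34           600 5.666667   FALSE

mn   <- keep[keep$compartment == "tumor", ]
grid <- quantize_density(estimate_kde(mn, c(0, 1000, 0, 1000), grid_n = 60,
                                      mask_points = tis$cells))
enrichment_at_threshold(tis$cells, grid, threshold = 80,
                        tumor_id = "tumor_07")
#>    cell_type n_inside n_outside fold_enrichment
#> 1      Tumor      132       468           0.976
#> 2 Macrophage       46       100           1.592
#> 3      Tcell       44       169           0.901
#> 4      Bcell       17        80           0.735
#> 5 Fibroblast       30       114           0.911
```

34 cGAS⁺ MN over 600 tumor cells give a score of 5.7 MN per 100 cells;
macrophages — placed at 3× density inside hotspots by the generator — are
the only type enriched (FE 1.59) in the ≥ 80th-percentile MN-density region,
while the other types sit near or below 1. Sweeping thresholds across a
cohort and testing FE against 1 is `threshold_sweep()`.

The `analysis/` directory holds six numbered drivers that walk the whole
pipeline on synthetic cohorts (tissue hotspots, CIN-gene discovery, cGAS
dependence, karyotype metrics, pseudobulk GSEA, cohort survival), each
writing its tables under `results/`.

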