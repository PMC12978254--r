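#!/usr/bin/env Rscript
# In-situ CIN readout and spatial hotspot enrichment.
#
# Simulates a cohort of stained tumor sections in which macrophages are
# placed at 2.5x density inside micronucleus-dense hotspots, scores cGAS+
# micronuclei per 100 tumor cells for each section, maps MN density by KDE,
# and sweeps hotspot thresholds (25th-95th percentile) to quantify immune
# cell-type fold enrichment. A matched unit-multiplier (null) cohort shows
# what the same analysis reports when no enrichment exists.

suppressMessages(library(cinflam))
dir.create("results", showWarnings = FALSE)
set.seed(1)

process_cohort <- function(multiplier, seed0, n_tumors = 12) {
  tumors <- list(); scores <- NULL
  for (i in seq_len(n_tumors)) {
    tis <- make_tissue(tissue_sim_config(hotspot_multiplier = multiplier,
                                         seed = seed0 + i))
    keep <- filter_mn_candidates(tis$foci, intensity_threshold = 0)
    scores <- rbind(scores, compute_mn_score(keep, tis$cells,
                                             sprintf("t%02d", i)))
    mn <- keep[keep$compartment == "tumor", ]
    if (nrow(mn) <= 10) next  # tumors with <= 10 MN are excluded
    g <- quantize_density(estimate_kde(mn, c(0, 1000, 0, 1000), grid_n = 60,
                                       mask_points = tis$cells))
    tumors[[length(tumors) + 1]] <- list(cells = tis$cells, grid = g)
  }
  list(sweep = threshold_sweep(tumors, 25:95), scores = scores,
       n_used = length(tumors))
}

enr <- process_cohort(c(Macrophage = 2.5), 100)
nul <- process_cohort(NULL, 900)

write.csv(enr$scores, "results/mn_scores.csv", row.names = FALSE)
write.csv(enr$sweep$summary, "results/hotspot_enrichment_summary.csv",
          row.names = FALSE)
write.csv(nul$sweep$summary, "results/hotspot_enrichment_null.csv",
          row.names = FALSE)

cat("MN scores (per 100 tumor cells): median",
    round(median(enr$scores$score), 2), "range",
    paste(round(range(enr$scores$score), 2), collapse = "-"), "\n")
mac <- subset(enr$sweep$summary, cell_type == "Macrophage")
cat(sprintf("Macrophage enrichment: median FE %.2f (across thresholds), %d/%d thresholds p < 0.05\n",
            median(mac$median_fe), sum(mac$p_value < 0.05, na.rm = TRUE),
            nrow(mac)))
mac0 <- subset(nul$sweep$summary, cell_type == "Macrophage")
cat(sprintf("Null cohort: median FE %.2f, %d/%d thresholds p < 0.05\n",
            median(mac0$median_fe), sum(mac0$p_value < 0.05, na.rm = TRUE),
            nrow(mac0)))
cat("Tables written to results/.\n")
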