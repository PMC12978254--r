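#!/usr/bin/env Rscript
# Discovery of genes whose expression scales with micronucleus burden.
#
# Simulates the isogenic clone panel (genotypes of escalating MN burden,
# 3 clones per engineered genotype, 3 batches), filters and normalizes the
# counts, fits the per-gene mixed model (expression ~ MN burden with clone
# and batch random intercepts), and derives the top-70 positive-slope
# signature. Ground truth lets us report slope recovery, null calibration
# and signature recall directly.
#
# Problem size: 1,000 genes (100 true CIN genes) to keep the driver quick;
# the acceptance script runs the full 2,000-gene configuration.

suppressMessages(library(cinflam))
dir.create("results", showWarnings = FALSE)

cfg <- expression_sim_config(n_genes = 1000, seed = 42)
sim <- make_isogenic_counts(cfg)
expr <- filter_and_normalize(sim$counts)
truth <- sim$truth[match(rownames(expr), sim$truth$gene), ]
meta <- data.frame(mn = sim$meta$mn, clone = sim$meta$clone,
                   batch = sim$meta$batch)

cat(sprintf("Fitting %d per-gene mixed models over %d samples...\n",
            nrow(expr), ncol(expr)))
assoc <- fit_mn_lmm_all(expr, meta)
assoc$true_slope <- truth$true_slope
write.csv(assoc, "results/mn_associations.csv", row.names = FALSE)

rec <- coef(lm(assoc$slope ~ assoc$true_slope))[2]
ks <- suppressWarnings(ks.test(assoc$p_value[truth$true_slope == 0],
                               "punif"))
cat(sprintf("Slope recovery (estimated ~ true): %.3f (1 = perfect)\n", rec))
cat(sprintf("Null-gene p-value KS test vs uniform: p = %.3f\n", ks$p.value))

sig <- derive_cin_mn_signature(assoc, k = 70)
write_gmt(list(CIN_MN = sig), "results/cin_mn_signature.gmt")
pos_true <- truth$gene[truth$is_cin & truth$true_slope > 0]
# at this problem size only ~50 positive-slope CIN genes exist, so a 70-gene
# signature cannot exceed ~70% purity; the full-size run is in acceptance
cat(sprintf("CIN-MN signature: %d genes, %.0f%% truly MN-associated (max attainable %.0f%%)\n",
            length(sig), 100 * mean(sig %in% pos_true),
            100 * min(1, length(pos_true) / length(sig))))
cat("Association table and GMT written to results/.\n")
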