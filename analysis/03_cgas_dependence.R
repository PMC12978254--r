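#!/usr/bin/env Rscript
# cGAS-dependent CIN-induced genes from a paired knockout design.
#
# Simulates two "cell lines" (independent seeds) with the 2x2 design
# (Cas9 / cGAS-KO by DMSO / MPS1i across 3 paired batches): 10% of genes
# are MPS1i-induced and half of those lose their induction in the knockout.
# Each line is classified (DESeq2 Wald test at padj <= 0.01 in Cas9 plus a
# paired per-batch fold-change t-test between genotypes at p <= 0.05), and
# consensus hits are intersected across lines, mirroring a two-line
# validation strategy.

suppressMessages(library(cinflam))
dir.create("results", showWarnings = FALSE)

lines <- list(OE33like = 7, SKGT4like = 8)
calls <- list()
for (nm in names(lines)) {
  sim <- make_ko_experiment(n_genes = 1500, induced_set = 1:150,
                            dependent_subset = 1:75, lfc = 2,
                            dependence_attenuation = 0.1,
                            nb_dispersion = 0.05, n_batches = 3,
                            seed = lines[[nm]])
  cl <- call_cgas_dependence(sim$counts, sim$meta)
  tr <- sim$truth[match(cl$gene, sim$truth$gene), ]
  dep <- cl$class == "cGAS_dependent_induced"
  cat(sprintf("%s: %d dependent-induced calls | sensitivity %.2f, FPR %.4f\n",
              nm, sum(dep),
              sum(dep & tr$dependent) / sum(tr$dependent),
              sum(dep & !tr$dependent) / sum(!tr$dependent)))
  write.csv(cl, sprintf("results/dependence_calls_%s.csv", nm),
            row.names = FALSE)
  calls[[nm]] <- cl
}

hits <- consensus_hits(calls)
write_gmt(list(consensus_cgas_dependent = hits),
          "results/consensus_hits.gmt")
shared_truth <- paste0("gene", sprintf("%04d", 1:75))
cat(sprintf("Consensus across lines: %d genes (%.0f%% of the shared truth set)\n",
            length(hits), 100 * mean(shared_truth %in% hits)))
cat("Note: with 3 paired batches the t gate has 2 degrees of freedom, which\n")
cat("caps per-line sensitivity well below 1 even at strong attenuation.\n")
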