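test_that("gene filter applies both the total and the nonzero-sample gate", {
  counts <- rbind(g1 = c(1, 1, 1, 1, 1, 0),  # total 5, nonzero 5 -> kept
                  g2 = c(4, 0, 0, 0, 0, 0),  # total 4 -> dropped
                  g3 = c(5, 0, 0, 0, 0, 0),  # nonzero in 1 < 4 -> dropped
                  g4 = c(2, 2, 2, 2, 2, 2))
  kept <- filter_genes(counts, min_total = 5, min_expressed_samples = 4)
  expect_setequal(rownames(kept), c("g1", "g4"))
})

test_that("per-batch log2 fold changes match hand-computed ratios", {
  meta <- data.frame(treatment = rep(c("DMSO", "MPS1i"), 3),
                     batch = rep(c("b1", "b2", "b3"), each = 2))
  counts <- matrix(1000L, 4, 6,
                   dimnames = list(paste0("g", 1:4), NULL))
  lfc <- per_batch_log2fc(counts, meta)
  expect_true(all(abs(lfc) < 1e-12))  # identical counts -> 0 in every batch
  # exact doubling with large counts -> ~1
  counts[, meta$treatment == "MPS1i"] <- 2000L
  lfc <- per_batch_log2fc(counts, meta)
  # size factors absorb part of a global doubling; rebuild with half the
  # genes doubled so the median-of-ratios reference stays put
  counts2 <- matrix(1000, 100, 6, dimnames = list(sprintf("g%03d", 1:100),
                                                  NULL))
  counts2[1:10, meta$treatment == "MPS1i"] <- 2000
  lfc2 <- per_batch_log2fc(counts2, meta)
  expect_equal(unname(lfc2[1, ]), rep(1, 3), tolerance = 0.01)
  expect_equal(unname(lfc2[50, ]), rep(0, 3), tolerance = 0.01)
  # random counts against a direct arithmetic oracle
  set.seed(7)
  counts3 <- matrix(rpois(600, 200), 100, 6,
                    dimnames = list(sprintf("g%03d", 1:100), NULL))
  lfc3 <- per_batch_log2fc(counts3, meta)
  sf <- size_factors(counts3)
  norm <- sweep(counts3, 2, sf, "/")
  manual <- log2((norm[17, 4] + 0.5) / (norm[17, 3] + 0.5))
  expect_equal(lfc3[17, "b2"], unname(manual))
})

test_that("differential expression is null for identical groups and calibrated", {
  set.seed(11)
  mu <- rexp(2000, 1 / 200)
  counts <- sapply(1:6, function(j) rnbinom(2000, mu = mu, size = 20))
  rownames(counts) <- sprintf("g%04d", 1:2000)
  cond <- rep(c("A", "B"), each = 3)
  de <- differential_expression(counts, cond, ref_level = "A")
  # simulated null: type-I error near nominal (absolute band)
  expect_lt(abs(mean(de$pvalue < 0.05, na.rm = TRUE) - 0.05), 0.02)
  expect_lt(abs(median(de$log2fc, na.rm = TRUE)), 0.05)
  # 4-fold induction is recovered
  counts2 <- counts
  counts2[1:100, 4:6] <- matrix(
    rnbinom(300, mu = rep(4 * mu[1:100], 3), size = 20), ncol = 3)
  de2 <- differential_expression(counts2, cond, ref_level = "A")
  expect_equal(median(de2$log2fc[1:100]), 2, tolerance = 0.15)
  expect_gt(mean(de2$padj[1:100] < 0.01), 0.9)
})

test_that("per-batch fold changes are invariant to scaling one sample's library", {
  set.seed(13)
  meta <- data.frame(treatment = rep(c("DMSO", "MPS1i"), 3),
                     batch = rep(c("b1", "b2", "b3"), each = 2))
  counts <- matrix(rpois(1200, 500), 200, 6,
                   dimnames = list(sprintf("g%03d", 1:200), NULL))
  lfc1 <- per_batch_log2fc(counts, meta)
  counts2 <- counts
  counts2[, 2] <- counts[, 2] * 3L
  lfc2 <- per_batch_log2fc(counts2, meta)
  # size factors absorb the scaling; only pseudocount effects remain
  expect_lt(max(abs(lfc1 - lfc2)), 0.01)
})

test_that("dependence classification applies all gates as specified", {
  genes <- paste0("g", 1:5)
  de <- data.frame(gene = genes,
                   base_mean = 100,
                   log2fc = c(2, 2, -2, 2, 2),
                   pvalue = 0.001,
                   padj = c(0.001, 0.001, 0.001, 0.02, 0.001))
  mk <- function(v) matrix(v, nrow = 5, ncol = 3, byrow = FALSE,
                           dimnames = list(genes, paste0("b", 1:3)))
  lfc_cas9 <- rbind(c(2.0, 2.1, 1.9),   # induced, attenuated in KO
                    c(2.0, 2.1, 1.9),   # induced identically in KO
                    -c(2.0, 2.1, 1.9),  # suppressed, attenuated in KO
                    c(2.0, 2.1, 1.9),   # padj 0.02 -> fails DE gate
                    c(2.0, 2.1, 1.9))   # KO *stronger* -> not dependent
  rownames(lfc_cas9) <- genes; colnames(lfc_cas9) <- paste0("b", 1:3)
  lfc_ko <- rbind(c(0.1, 0.4, 0.0),
                  c(2.0, 2.1, 1.9),
                  -c(0.1, 0.4, 0.0),
                  c(0.1, 0.4, 0.0),
                  c(4.0, 4.3, 3.9))
  rownames(lfc_ko) <- genes; colnames(lfc_ko) <- paste0("b", 1:3)
  calls <- classify_cgas_dependence(de, lfc_cas9, lfc_ko)
  expect_equal(calls$class,
               c("cGAS_dependent_induced", "cGAS_independent_changed",
                 "cGAS_dependent_suppressed", "unchanged",
                 "cGAS_independent_changed"))
  # the paired test equals the textbook closed form on printed pairs
  expect_equal(calls$paired_t_p[1],
               t.test(lfc_cas9[1, ], lfc_ko[1, ], paired = TRUE)$p.value)
})

test_that("consensus intersects dependence calls across lines", {
  mk <- function(genes, cls) data.frame(gene = genes, class = cls)
  a <- mk(c("g1", "g2", "g3"), rep("cGAS_dependent_induced", 3))
  b <- mk(c("g2", "g3", "g4"), rep("cGAS_dependent_induced", 3))
  expect_setequal(consensus_hits(list(a, b)), c("g2", "g3"))
  expect_equal(consensus_hits(list(a, mk("g9", "cGAS_dependent_induced"))),
               character(0))
  expect_setequal(consensus_hits(list(a, a)), c("g1", "g2", "g3"))
})

test_that("end-to-end calls recover an attenuated induced set at the df-2 power ceiling", {
  sim <- make_ko_experiment(n_genes = 600, induced_set = 1:60,
                            dependent_subset = 1:30,
                            lfc = 2, dependence_attenuation = 0,
                            nb_dispersion = 0.05, n_batches = 3, seed = 5)
  calls <- call_cgas_dependence(sim$counts, sim$meta)
  truth <- sim$truth[match(calls$gene, sim$truth$gene), ]
  dep_called <- calls$class == "cGAS_dependent_induced"
  sens <- sum(dep_called & truth$dependent) / sum(truth$dependent)
  fpr <- sum(dep_called & !truth$dependent) / sum(!truth$dependent)
  # with 3 pairs the t gate has df 2: noncentrality 2/(0.645/sqrt(3)) gives
  # power 0.77, an upper bound on sensitivity at dispersion 0.05
  expect_gte(sens, 0.5)
  expect_lte(sens, 0.85)
  expect_lte(fpr, 0.01)
  # induced-but-independent genes land in the independent class
  ind_only <- truth$induced & !truth$dependent
  expect_gt(mean(calls$class[ind_only] == "cGAS_independent_changed"), 0.8)
})
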