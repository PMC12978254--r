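test_that("filtering and normalization follow the stated gates and scaling", {
  counts <- rbind(g1 = rep(10, 6),            # total 60 -> kept
                  g2 = c(49, 0, 0, 0, 0, 0),  # total 49 -> dropped
                  g3 = c(60, 0, 0, 0, 0, 0),  # nonzero in 1 < 4 -> dropped
                  g4 = rep(20, 6))
  expr <- filter_and_normalize(counts, min_total = 50)
  expect_setequal(rownames(expr), c("g1", "g4"))
  # equal counts across samples give equal normalized values per gene
  expect_true(all(apply(expr, 1, function(v) diff(range(v)) == 0)))
  # doubling one sample's library doubles its relative size factor and
  # leaves normalized values unchanged up to a common rescaling
  set.seed(1)
  counts2 <- matrix(rpois(600, 100), 100, 6,
                    dimnames = list(sprintf("g%03d", 1:100), NULL))
  sf <- size_factors(counts2)
  counts3 <- counts2
  counts3[, 4] <- counts2[, 4] * 2L
  sf3 <- size_factors(counts3)
  expect_equal((sf3[4] / sf3[1]) / (sf[4] / sf[1]), 2, tolerance = 1e-8)
  norm2 <- sweep(counts2, 2, sf, "/")
  norm3 <- sweep(counts3, 2, sf3, "/")
  ratio <- norm3 / norm2
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("mixed model recovers an exact linear relationship and the OLS limit", {
  meta <- expand.grid(clone = paste0("cl", 1:3), batch = paste0("b", 1:3))
  meta$mn <- c(2, 5, 9)[as.integer(factor(meta$clone))]
  y <- 2 + 0.3 * meta$mn
  fit <- fit_mn_lmm(y + rnorm(9, 0, 1e-8), meta$mn, meta$clone, meta$batch)
  expect_equal(fit$slope, 0.3, tolerance = 1e-4)
  # pure iid noise: variance components collapse and the slope equals OLS
  set.seed(2)
  y2 <- 1 + 0.1 * meta$mn + rnorm(9, 0, 0.5)
  fit2 <- fit_mn_lmm(y2, meta$mn, meta$clone, meta$batch)
  ols <- unname(coef(lm(y2 ~ meta$mn))[2])
  expect_equal(fit2$slope, ols, tolerance = 1e-6)
  # guards
  expect_error(fit_mn_lmm(y, meta$mn, rep("cl1", 9), meta$batch),
               "2 clones")
})

test_that("per-gene association p-values are calibrated on null genes", {
  cfg <- expression_sim_config(n_genes = 250, frac_cin_genes = 0, seed = 31)
  sim <- make_isogenic_counts(cfg)
  expr <- filter_and_normalize(sim$counts)
  meta <- data.frame(mn = sim$meta$mn, clone = sim$meta$clone,
                     batch = sim$meta$batch)
  assoc <- fit_mn_lmm_all(expr, meta)
  expect_gt(ks.test(assoc$p_value, "punif")$p.value, 0.01)
})

test_that("signature derivation ranks positive slopes by significance", {
  assoc <- data.frame(gene = paste0("g", 1:6),
                      slope = c(0.5, -0.5, 0.3, 0.2, 0.4, 0.1),
                      p_value = c(0.001, 1e-6, 0.01, 0.001, 0.5, 0.2))
  expect_equal(derive_cin_mn_signature(assoc, k = 1), "g1")
  expect_equal(derive_cin_mn_signature(assoc, k = 3),
               c("g1", "g4", "g3"))  # g2 excluded (negative slope)
  expect_warning(sig <- derive_cin_mn_signature(assoc, k = 10), "positive")
  expect_length(sig, 5)
  # ties on p broken by larger slope
  assoc2 <- data.frame(gene = c("a", "b"), slope = c(0.1, 0.9),
                       p_value = c(0.01, 0.01))
  expect_equal(derive_cin_mn_signature(assoc2, k = 1), "b")
})

test_that("ssGSEA scoring is extremal, rank-based and matches the oracle", {
  set.seed(4)
  expr <- matrix(rnorm(200 * 5), 200, 5,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:5)))
  sig <- rownames(expr)[order(expr[, 1], decreasing = TRUE)[1:10]]
  s <- ssgsea_score(expr, sig, normalize = FALSE)
  # signature at the top ranks of sample 1 scores above any other placement
  other <- replicate(20, ssgsea_score(expr,
                                      sample(rownames(expr), 10),
                                      normalize = FALSE)[1])
  expect_true(all(s[1] > other))
  # invariant under strictly monotone transforms
  expr_pos <- abs(expr) + 1
  expect_equal(ssgsea_score(expr_pos, sig, normalize = FALSE),
               ssgsea_score(expr_pos^3, sig, normalize = FALSE))
  # matches the independent running-sum oracle
  in_set <- rownames(expr) %in% sig
  expect_equal(unname(s[2]), oracle_ssgsea(expr[, 2], in_set))
  # gene order in the matrix does not matter; absent genes warn
  perm <- sample(nrow(expr))
  expect_equal(ssgsea_score(expr[perm, ], sig, normalize = FALSE), s)
  expect_warning(s2 <- ssgsea_score(expr, c(sig, "not_a_gene"),
                                    normalize = FALSE), "absent")
  expect_equal(s2, s)
})

test_that("skew is the score difference with the expected ordering", {
  expect_equal(myeloid_lymphoid_skew(c(1, 2), c(1, 1)), c(0, 1))
  sim <- make_cohort(n_tumors = 300, seed = 6)
  sk <- myeloid_lymphoid_skew(sim$cohort$myeloid, sim$cohort$lymphoid)
  expect_equal(sk, sim$cohort$skew)
})

test_that("exclusive compartment signatures match hand enumeration", {
  dge <- rbind(
    data.frame(cluster = "Mac", versus = "T", gene = c("mA", "mB", "both"),
               log2fc = 2, padj = c(0.001, 0.01, 0.001)),
    data.frame(cluster = "T", versus = "Mac", gene = c("tA", "both"),
               log2fc = 2, padj = c(0.005, 0.002)),
    data.frame(cluster = "T", versus = "Mac", gene = "tB",
               log2fc = -2, padj = 0.001),           # down, not up
    data.frame(cluster = "Mac", versus = "DC", gene = "mC",
               log2fc = 2, padj = 0.2))              # not significant
  comp <- c(Mac = "myeloid", T = "lymphoid", DC = "myeloid")
  expect_warning(
    expect_warning(sigs <- derive_compartment_signatures(dge, comp,
                                                         top_n = 50),
                   "myeloid"),
    "lymphoid")
  # "both" is up in myeloid and lymphoid: excluded from each
  expect_setequal(sigs$myeloid, c("mA", "mB"))
  expect_setequal(sigs$lymphoid, "tA")
  # ranking by best padj and truncation
  s1 <- derive_compartment_signatures(dge, comp, top_n = 1)
  expect_equal(s1$myeloid, "mA")
})
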