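test_that("response interaction recovers constructed slope differences", {
  set.seed(1)
  n <- 100
  mn <- runif(n, 0, 12)
  resp <- rep(c("R", "NR"), length.out = n)
  slope <- ifelse(resp == "NR", 0.7, 0.2)
  y <- 1 + slope * mn + rnorm(n, 0, 0.5)
  fit <- response_interaction(y, mn, resp)
  expect_equal(fit$slope_difference, 0.5, tolerance = 0.15)
  expect_lt(fit$interaction_p, 0.01)
  # identical slopes: difference near 0 (the p-value itself is uniform
  # under the null, so only the estimate is pinned down)
  y0 <- 1 + 0.4 * mn + rnorm(n, 0, 0.5)
  fit0 <- response_interaction(y0, mn, resp)
  expect_equal(fit0$slope_difference, 0, tolerance = 0.12)
  expect_gt(fit0$interaction_p, 0.005)
  # other response classes are excluded; degenerate class flagged
  resp2 <- resp; resp2[1:10] <- "other"
  expect_s3_class(response_interaction(y, mn, resp2), "data.frame")
  mn3 <- mn; mn3[resp == "R"] <- 4
  expect_warning(fit3 <- response_interaction(y, mn3, resp), "degenerate")
  expect_true(fit3$degenerate)
})

test_that("cGAS-STING interaction classifier follows its gates", {
  set.seed(2)
  n <- 150
  cin <- rnorm(n); sting <- rnorm(n)
  purity <- runif(n, 0.3, 1); leuko <- runif(n, 0, 0.5)
  # pure CIN effect without interaction: not dependent
  y_main <- 2 * cin + rnorm(n, 0, 0.3)
  cls_main <- cin_cgassting_interaction(y_main, cin, sting, purity, leuko)
  expect_equal(cls_main$class, "not_dependent")
  # multiplicative construction: enriched-dependent
  y_int <- cin + cin * sting + rnorm(n, 0, 0.3)
  cls_int <- cin_cgassting_interaction(y_int, cin, sting, purity, leuko)
  expect_equal(cls_int$class, "enriched_dependent")
  # mirror construction: depleted-dependent
  y_neg <- -cin - cin * sting + rnorm(n, 0, 0.3)
  expect_equal(cin_cgassting_interaction(y_neg, cin, sting, purity,
                                         leuko)$class,
               "depleted_dependent")
  # matrix input classifies row-wise and matches lm() p-values
  m <- rbind(a = y_main, b = y_int)
  colnames(m) <- paste0("s", 1:n)
  cls_m <- cin_cgassting_interaction(m, cin, sting, purity, leuko)
  expect_equal(cls_m$class, c("not_dependent", "enriched_dependent"))
  ref <- summary(lm(y_int ~ cin * sting + purity + leuko))$coefficients
  expect_equal(cls_int$interaction_p, ref["cin:sting", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("covariate-adjusted score agreement differs from marginal correlation", {
  set.seed(3)
  n <- 200
  cin <- rnorm(n)
  purity <- runif(n); leuko <- runif(n)
  exact <- cin_score_agreement(2 * cin + rnorm(n, 0, 1e-6), cin, purity,
                               leuko)
  expect_equal(exact$coefficient, 2, tolerance = 1e-5)
  expect_lt(exact$p_value, 1e-10)
  # confounded construction: marginal and adjusted estimates disagree
  target <- 1 * cin + 4 * leuko + rnorm(n, 0, 0.2)
  cin_c <- cin + 2 * leuko   # confounded CIN measure
  adj <- cin_score_agreement(target, cin_c, purity, leuko)$coefficient
  marg <- unname(coef(lm(target ~ cin_c))[2])
  expect_gt(abs(marg - adj), 0.1)
})

test_that("KM equals empirical survival without censoring; log-rank matches hand computation", {
  time <- c(3, 5, 7, 2, 9, 12, 4, 8)
  ev <- rep(1, 8)
  grp <- rep("A", 8)
  km <- km_logrank(time, ev, grp)
  s <- summary(km$fit)
  emp <- sapply(s$time, function(tt) mean(time > tt))
  expect_equal(s$surv, emp)
  # 6-subject two-group toy: compare against the tabulated O-E computation
  t2 <- c(1, 3, 5, 2, 4, 6)
  e2 <- c(1, 1, 0, 1, 1, 1)
  g2 <- rep(c("ctrl", "trt"), each = 3)
  km2 <- km_logrank(t2, e2, g2)
  expect_equal(km2$chisq, oracle_logrank(t2, e2, g2), tolerance = 1e-10)
  # identical groups give statistic 0
  km0 <- km_logrank(rep(t2, 2), rep(e2, 2), rep(c("x", "y"), each = 6))
  expect_equal(km0$chisq, 0, tolerance = 1e-10)
  expect_equal(km0$p_value, 1)
  # log-rank is invariant under monotone time transformations
  km_log <- km_logrank(log(t2 + 1), e2, g2)
  expect_equal(km_log$chisq, km2$chisq)
  # pairwise tests appear for > 2 groups
  km3 <- km_logrank(c(t2, 2, 6, 7), c(e2, 1, 1, 0),
                    c(g2, rep("extra", 3)), reference = "ctrl")
  expect_equal(nrow(km3$pairwise), 2)
})

test_that("the vectorized log-rank scan agrees with survdiff at every cutpoint", {
  set.seed(4)
  n <- 60
  score <- rnorm(n)
  time <- rexp(n, 0.1 * exp(0.5 * score))
  ev <- rbinom(n, 1, 0.8)
  ms <- maxstat_cutpoint(score, time, ev, n_perm = 50, seed = 1)
  for (i in seq(1, nrow(ms$candidates), by = 7)) {
    cp <- ms$candidates$cutpoint[i]
    sd0 <- survival::survdiff(survival::Surv(time, ev) ~ I(score > cp))
    expect_equal(ms$candidates$z[i]^2, sd0$chisq, tolerance = 1e-8)
  }
})

test_that("maxstat recovers a step-change threshold and handles ties", {
  set.seed(5)
  n <- 200
  score <- runif(n, 0, 10)
  rate <- ifelse(score > 6, 0.4, 0.05)
  time <- rexp(n, rate)
  ev <- rep(1, n)
  ms <- maxstat_cutpoint(score, time, ev, n_perm = 200, seed = 2)
  expect_lt(abs(ms$cutpoint - 6), 1)
  expect_lt(ms$p_value, 0.01)
  # duplicated scores collapse to one candidate per unique value
  score2 <- rep(1:5, each = 40)
  ms2 <- maxstat_cutpoint(score2, time, ev, n_perm = 20, seed = 3)
  expect_lte(nrow(ms2$candidates), 4)
  expect_equal(anyDuplicated(ms2$candidates$cutpoint), 0)
})

test_that("nested median stratification splits as specified", {
  s4 <- nested_median_stratify(c(1, 2, 3, 4), c(10, 1, 1, 10))
  expect_setequal(as.character(s4), c("CIN_low_My", "CIN_low_Ly",
                                      "CIN_high_Ly", "CIN_high_My"))
  # values at the exact median go low
  s3 <- nested_median_stratify(c(1, 2, 3), c(5, 5, 9))
  expect_equal(as.character(s3)[2], "CIN_low_Ly")
  # near-balanced strata on a continuous cohort
  sim <- make_cohort(n_tumors = 200, seed = 7)
  st <- nested_median_stratify(sim$cohort$cin_mn_score, sim$cohort$skew)
  expect_true(all(abs(table(st) - 50) <= 1))
})

test_that("Cox recovery, null behavior and degenerate flags", {
  set.seed(8)
  n <- 1000
  high <- rep(c(FALSE, TRUE), each = n / 2)
  time <- rexp(n, 0.1 * ifelse(high, 2, 1))
  ev <- rep(1, n)
  fit <- cox_univariate(high, time, ev)
  expect_equal(fit$hr, 2, tolerance = 0.1)
  expect_true(fit$ci_lower < 2 && fit$ci_upper > 2)
  # labels independent of survival: HR near 1, p large on average
  fit0 <- cox_univariate(sample(high), time, ev)
  expect_equal(fit0$hr, 1, tolerance = 0.25)
  # a group without events is flagged
  ev2 <- ifelse(high, 0, 1)
  expect_warning(fitd <- cox_univariate(high, time, ev2), "no events")
  expect_true(fitd$flagged)
})
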