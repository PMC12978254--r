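test_that("affine projection matches matrix arithmetic", {
  pts <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  ident <- cbind(diag(2), c(0, 0))
  expect_equal(project_points(pts, ident), pts)
  shift <- cbind(diag(2), c(10, -5))
  out <- project_points(pts, shift)
  expect_equal(out$x, pts$x + 10)
  expect_equal(out$y, pts$y - 5)
  # 90 degree counter-clockwise rotation of the unit square corners
  rot <- cbind(matrix(c(0, 1, -1, 0), 2, 2), c(0, 0))
  out <- project_points(pts, rot)
  expect_equal(out$x, c(0, 0, -1, -1))
  expect_equal(out$y, c(0, 1, 1, 0))
})

test_that("KDE mode, normalization and flat limit behave as expected", {
  set.seed(2)
  pts <- data.frame(x = rnorm(500, 300, 20), y = rnorm(500, 600, 20))
  g <- estimate_kde(pts, c(0, 1000, 0, 1000), grid_n = 100)
  idx <- which(g$z == max(g$z), arr.ind = TRUE)
  cell <- c(diff(g$x[1:2]), diff(g$y[1:2]))
  expect_lt(abs(g$x[idx[1]] - 300), 20 + cell[1])
  expect_lt(abs(g$y[idx[2]] - 600), 20 + cell[2])
  # density integrates to ~1 over the field
  expect_equal(sum(g$z) * cell[1] * cell[2], 1, tolerance = 0.01)
  # uniform points, interior of the grid: max/min density ratio near 1
  unif <- data.frame(x = runif(5000, 0, 1000), y = runif(5000, 0, 1000))
  gu <- estimate_kde(unif, c(0, 1000, 0, 1000), grid_n = 50,
                     bandwidth = 150)
  interior <- gu$z[gu$x > 300 & gu$x < 700, gu$y > 300 & gu$y < 700]
  expect_lt(max(interior) / min(interior), 1.3)
  # coincident points trigger the bandwidth floor, not an error
  co <- data.frame(x = rep(500, 20), y = rep(500, 20))
  expect_warning(gc <- estimate_kde(co, c(0, 1000, 0, 1000), grid_n = 20),
                 "floor")
  expect_true(all(is.finite(gc$z)))
})

test_that("percentile quantization matches the counting definition", {
  g <- manual_grid(matrix(NA_integer_, 10, 10))
  # constant density collapses to a single bin
  g$z <- matrix(1, 10, 10)
  expect_true(all(quantize_density(g)$percentile == 100))
  # strictly increasing over 100 nodes gives bins 1..100
  g$z <- matrix(seq_len(100), 10, 10)
  q <- quantize_density(g)
  expect_setequal(as.vector(q$percentile), 1:100)
  expect_equal(q$percentile[order(g$z)], 1:100)
  # random grid with ties: percentile equals ceiling(100 * #(<= d) / N)
  set.seed(3)
  g$z <- matrix(sample(1:20, 100, replace = TRUE), 10, 10)
  q <- quantize_density(g)
  manual <- matrix(0L, 10, 10)
  for (i in 1:10) for (j in 1:10)
    manual[i, j] <- as.integer(ceiling(100 * sum(g$z <= g$z[i, j]) / 100))
  expect_identical(q$percentile, manual)
})

test_that("fold enrichment reproduces the direct counting example", {
  # 20x20 nodes; the x > 10 half is the >= 50th percentile region
  perc <- matrix(10L, 20, 20)
  perc[11:20, ] <- 90L
  g <- manual_grid(perc)
  # 400 cells on node coordinates: 100 inside, 300 outside;
  # type A: 10 inside, 10 outside -> FE = (10/100)/(10/300) = 3
  inside_xy <- expand.grid(x = 11:20, y = 1:20)[1:100, ]
  outside_xy <- expand.grid(x = 1:10, y = 1:20)[rep(1:200,
                                                    length.out = 300), ]
  cells <- data.frame(x = c(inside_xy$x, outside_xy$x),
                      y = c(inside_xy$y, outside_xy$y),
                      compartment = "stroma",
                      cell_type = c(rep("A", 10), rep("B", 90),
                                    rep("A", 10), rep("B", 290)))
  rec <- enrichment_at_threshold(cells, g, 50)
  expect_equal(rec$fold_enrichment[rec$cell_type == "A"], 3.0)
  expect_equal(rec$total_inside[1], 100)
  # a type present only inside is excluded
  cells2 <- rbind(cells, data.frame(x = 15, y = 5, compartment = "stroma",
                                    cell_type = "OnlyIn"))
  rec2 <- enrichment_at_threshold(cells2, g, 50)
  expect_false("OnlyIn" %in% rec2$cell_type)
  # an empty hotspot yields no records
  expect_equal(nrow(enrichment_at_threshold(cells, g, 95)), 0)
})

test_that("pipeline enrichment equals brute-force counting on synthetic tissue", {
  for (seed in c(31, 32)) {
    tis <- make_tissue(tissue_sim_config(
      n_tumor_cells = 300, n_stromal_cells = 300,
      hotspot_multiplier = c(Macrophage = 2.5), seed = seed))
    mn <- filter_mn_candidates(tis$foci)
    mn <- mn[mn$compartment == "tumor", ]
    g <- quantize_density(estimate_kde(mn, c(0, 1000, 0, 1000), grid_n = 40,
                                       mask_points = tis$cells))
    for (th in c(30, 60, 90)) {
      got <- enrichment_at_threshold(tis$cells, g, th)
      want <- oracle_enrichment(tis$cells, g, th)
      got <- got[order(got$cell_type), ]
      want <- want[order(want$cell_type), ]
      expect_equal(got$cell_type, want$cell_type)
      expect_equal(got$fold_enrichment, want$fold_enrichment)
    }
  }
})

test_that("fold enrichment is invariant under a rigid transform of the section", {
  tis <- make_tissue(tissue_sim_config(n_tumor_cells = 250,
                                       n_stromal_cells = 250, seed = 13))
  mn <- filter_mn_candidates(tis$foci)
  mn <- mn[mn$compartment == "tumor", ]
  fe_of <- function(cells, mn, bounds) {
    g <- quantize_density(estimate_kde(mn, bounds, grid_n = 40,
                                       bandwidth = c(60, 60)))
    enrichment_at_threshold(cells, g, 70)
  }
  base <- fe_of(tis$cells, mn, c(0, 1000, 0, 1000))
  rot <- cbind(matrix(c(0, 1, -1, 0), 2, 2), c(1000, 0))  # 90 deg + shift
  cells_r <- project_points(tis$cells, rot)
  mn_r <- project_points(mn, rot)
  rotated <- fe_of(cells_r, mn_r, c(0, 1000, 0, 1000))
  m <- merge(base, rotated, by = "cell_type")
  expect_equal(m$fold_enrichment.x, m$fold_enrichment.y)
})

test_that("threshold sweep summarizes across tumors and degrades gracefully", {
  tumors <- lapply(c(41, 42, 43), function(s) {
    tis <- make_tissue(tissue_sim_config(n_tumor_cells = 250,
                                         n_stromal_cells = 250, seed = s))
    mn <- filter_mn_candidates(tis$foci)
    mn <- mn[mn$compartment == "tumor", ]
    g <- quantize_density(estimate_kde(mn, c(0, 1000, 0, 1000), grid_n = 40,
                                       mask_points = tis$cells))
    list(cells = tis$cells, grid = g)
  })
  sw <- threshold_sweep(tumors, thresholds = c(40, 70))
  expect_true(all(c("mean_fe", "median_fe", "p_value") %in%
                    colnames(sw$summary)))
  expect_true(all(sw$summary$n_tumors <= 3))
  # a single tumor cannot support the t-test
  sw1 <- threshold_sweep(tumors[1], thresholds = 70)
  expect_true(all(is.na(sw1$summary$p_value)))
})
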