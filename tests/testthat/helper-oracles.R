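# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. These are deliberately written as plain loops
# over first-principles definitions, sharing no code with R/.

# Nearest-node percentile per cell, by explicit per-cell search.
oracle_cell_percentiles <- function(cells, grid) {
  perc <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ix <- which.min(abs(grid$x - cells$x[i]))
    iy <- which.min(abs(grid$y - cells$y[i]))
    perc[i] <- grid$percentile[ix, iy]
  }
  perc
}

# Fold enrichment by explicit per-cell counting, given each cell's nearest
# grid node percentile (recomputed here from scratch unless supplied).
oracle_enrichment <- function(cells, grid, threshold, perc = NULL) {
  keep0 <- cells$compartment != "artifact" & !is.na(cells$cell_type)
  cells <- cells[keep0, ]
  if (is.null(perc)) perc <- oracle_cell_percentiles(cells, grid)
  keep <- !is.na(perc)
  cells <- cells[keep, ]; perc <- perc[keep]
  inside <- perc >= threshold
  if (sum(inside) == 0 || sum(!inside) == 0) return(NULL)
  out <- NULL
  for (tt in unique(cells$cell_type)) {
    ti <- sum(cells$cell_type == tt & inside)
    to <- sum(cells$cell_type == tt & !inside)
    if (ti == 0 || to == 0) next
    fe <- (ti / sum(inside)) / (to / sum(!inside))
    out <- rbind(out, data.frame(cell_type = tt, threshold = threshold,
                                 fold_enrichment = fe))
  }
  out
}

# Karyotype scores from first principles.
oracle_aneuploidy <- function(cn, sizes, expected) {
  per_cell <- numeric(nrow(cn))
  for (i in seq_len(nrow(cn))) {
    num <- 0
    for (j in seq_len(ncol(cn)))
      num <- num + abs(cn[i, j] - expected[j]) * sizes[j]
    per_cell[i] <- num / sum(sizes)
  }
  per_cell
}

oracle_heterogeneity <- function(cn, sizes) {
  n <- nrow(cn)
  per_bin <- numeric(ncol(cn))
  for (j in seq_len(ncol(cn))) {
    disc <- 0; tot <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      tot <- tot + 1
      if (cn[a, j] != cn[b, j]) disc <- disc + 1
    }
    per_bin[j] <- disc / tot
  }
  list(per_bin = per_bin,
       sample = sum(per_bin * sizes) / sum(sizes))
}

oracle_breakpoints <- function(cn, chrom, sizes) {
  out <- numeric(nrow(cn))
  for (i in seq_len(nrow(cn))) {
    k <- 0
    for (j in seq_len(ncol(cn) - 1))
      if (chrom[j] == chrom[j + 1] && cn[i, j] != cn[i, j + 1]) k <- k + 1
    out[i] <- k / (sum(sizes) / 1e6)
  }
  out
}

# Weighted KS enrichment score by the full running-sum definition.
oracle_gsea_es <- function(metric, in_set) {
  ord <- order(-metric, names(metric))
  m <- abs(metric[ord]); s <- in_set[ord]
  p_hit <- cumsum(m * s) / sum(m[s])
  p_miss <- cumsum(!s) / sum(!s)
  run <- p_hit - p_miss
  unname(run[which.max(abs(run))])
}

# ssGSEA score for one sample by the full running-sum definition.
oracle_ssgsea <- function(x, in_set, alpha = 0.25) {
  r <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  s <- in_set[ord]
  w <- r[ord]^alpha
  cdf_in <- cumsum(ifelse(s, w, 0)) / sum(w[s])
  cdf_out <- cumsum(!s) / sum(!s)
  sum(cdf_in - cdf_out)
}

# Two-group log-rank chi-square by explicit time-point tabulation.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in ts) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small deterministic segmented-cell / foci tables.
toy_cells <- function() {
  data.frame(
    cell_id = paste0("c", 1:8),
    x = c(1, 2, 3, 4, 5, 6, 7, 8), y = rep(1, 8),
    compartment = c(rep("tumor", 4), rep("stroma", 3), "artifact"),
    cell_type = c(rep("Tumor", 4), "Macrophage", "Tcell", "Tcell", NA),
    cgas_intensity = c(10, 20, 30, 40, 5, 6, 7, 8),
    sting_intensity = rep(4, 8),
    autofluorescence = c(2, 2, 2, 2, 1, 2, 2, 2),
    stringsAsFactors = FALSE)
}

toy_foci <- function() {
  data.frame(
    focus_id = paste0("f", 1:5),
    x = 1:5, y = rep(1, 5),
    area = c(0.1, 0.25, 5.0, 7.5, 8.0),
    cgas_intensity = c(50, 50, 50, 50, 50),
    compartment = rep("tumor", 5),
    stringsAsFactors = FALSE)
}

# Construct a density_grid directly from a percentile matrix on integer
# node coordinates, for exact counting tests.
manual_grid <- function(percentile) {
  structure(list(x = seq_len(nrow(percentile)),
                 y = seq_len(ncol(percentile)),
                 z = percentile + 0,
                 mask = matrix(TRUE, nrow(percentile), ncol(percentile)),
                 percentile = percentile),
            class = "density_grid")
}
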