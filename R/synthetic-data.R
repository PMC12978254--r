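# Synthetic-data generators. Every downstream analysis in this package is
# exercised on data from these generators, whose ground truth (true
# enrichments, slopes, dependence classes, karyotypes, hazard coefficients)
# is returned alongside the data so that parameter recovery can be measured.

# Run expr with a locally seeded RNG, restoring any prior global state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration for the tissue simulator
#'
#' Describes a simulated stained tissue section: tumor and stromal cells
#' scattered over a rectangular field, with a set of isotropic Gaussian
#' "CIN hotspots" inside which micronuclei arise at an elevated rate and
#' selected immune cell types are present at increased density.
#'
#' @param n_tumor_cells,n_stromal_cells Cell counts (> 0 tumor cells required).
#' @param field_size Numeric length-2, field width and height in micrometers.
#' @param n_hotspots Number of hotspot centers.
#' @param hotspot_sigma Gaussian hotspot radius parameter (micrometers). A cell
#'   is "inside" a hotspot when the kernel weight exceeds 1/2, i.e. within
#'   \code{sigma * sqrt(2 * log(2))} of a center.
#' @param mn_rate_background,mn_rate_hotspot Expected cGAS+ micronuclei per
#'   tumor cell outside/inside hotspots.
#' @param mn_rate_stromal Expected stromal cGAS+ foci per stromal cell.
#' @param cell_type_proportions Named baseline fractions of stromal cell types
#'   (must sum to 1).
#' @param hotspot_multiplier Named relative density multipliers (> 0) applied
#'   inside hotspots; types not named default to 1.
#' @param frac_area_outliers Fraction of foci drawn with areas outside the
#'   0.25--7.5 um^2 detection window, to exercise area filtering.
#' @param artifact_fraction Fraction of extra cells labeled as artifact
#'   (e.g. necrotic debris), which downstream scoring must ignore.
#' @param seed Integer seed.
#' @return A list of class \code{tissue_sim_config}.
#' @export
tissue_sim_config <- function(n_tumor_cells = 600,
                              n_stromal_cells = 600,
                              field_size = c(1000, 1000),
                              n_hotspots = 3,
                              hotspot_sigma = 100,
                              mn_rate_background = 0.02,
                              mn_rate_hotspot = 0.50,
                              mn_rate_stromal = 0.005,
                              cell_type_proportions = c(Macrophage = 0.25,
                                                        Tcell = 0.35,
                                                        Bcell = 0.15,
                                                        Fibroblast = 0.25),
                              hotspot_multiplier = NULL,
                              frac_area_outliers = 0.2,
                              artifact_fraction = 0.02,
                              seed = 1L) {
  if (n_tumor_cells <= 0) stop("n_tumor_cells must be > 0")
  if (n_stromal_cells < 0) stop("n_stromal_cells must be >= 0")
  if (length(field_size) != 2L || any(field_size <= 0))
    stop("field_size must be two positive lengths (um)")
  .check_scalar(mn_rate_background, "mn_rate_background", 0)
  .check_scalar(mn_rate_hotspot, "mn_rate_hotspot", 0)
  .check_scalar(mn_rate_stromal, "mn_rate_stromal", 0)
  if (abs(sum(cell_type_proportions) - 1) > 1e-8)
    stop("cell_type_proportions must sum to 1")
  mult <- stats::setNames(rep(1, length(cell_type_proportions)),
                          names(cell_type_proportions))
  if (!is.null(hotspot_multiplier)) {
    if (any(hotspot_multiplier <= 0)) stop("hotspot multipliers must be > 0")
    unknown <- setdiff(names(hotspot_multiplier), names(mult))
    if (length(unknown)) stop("unknown cell types in hotspot_multiplier: ",
                              paste(unknown, collapse = ", "))
    mult[names(hotspot_multiplier)] <- hotspot_multiplier
  }
  structure(list(n_tumor_cells = n_tumor_cells,
                 n_stromal_cells = n_stromal_cells,
                 field_size = as.numeric(field_size),
                 n_hotspots = n_hotspots,
                 hotspot_sigma = hotspot_sigma,
                 mn_rate_background = mn_rate_background,
                 mn_rate_hotspot = mn_rate_hotspot,
                 mn_rate_stromal = mn_rate_stromal,
                 cell_type_proportions = cell_type_proportions,
                 hotspot_multiplier = mult,
                 frac_area_outliers = frac_area_outliers,
                 artifact_fraction = artifact_fraction,
                 seed = seed),
            class = "tissue_sim_config")
}

# Hotspot membership: kernel weight > 1/2 for any center.
.in_hotspot <- function(x, y, centers, sigma) {
  if (is.null(centers) || nrow(centers) == 0L) return(rep(FALSE, length(x)))
  r <- sigma * sqrt(2 * log(2))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(nrow(centers))) {
    inside <- inside |
      ((x - centers[k, 1])^2 + (y - centers[k, 2])^2 <= r^2)
  }
  inside
}

#' Simulate a stained tissue section with CIN hotspots
#'
#' Places tumor and stromal cells in a rectangular field. Stromal cell types
#' are placed with density multiplied by their hotspot multiplier inside
#' Gaussian hotspots (rejection sampling), so the realized spatial point
#' pattern carries the configured cell-type enrichment. Micronuclei are drawn
#' per tumor cell as Poisson counts at the background rate, or the hotspot
#' rate for cells inside a hotspot, and jittered around the parent cell.
#'
#' The returned truth contains, per cell type, the exact expected fold
#' enrichment implied by the configuration, computed from the hotspot area
#' fraction by numerical integration of the hotspot indicator over the field.
#'
#' @param cfg A \code{\link{tissue_sim_config}}.
#' @return List with \code{cells} (segmented-cell table), \code{foci}
#'   (candidate focus table) and \code{truth}.
#' @export
make_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "tissue_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$field_size
    centers <- if (cfg$n_hotspots > 0) {
      cbind(stats::runif(cfg$n_hotspots, 0.15 * fs[1], 0.85 * fs[1]),
            stats::runif(cfg$n_hotspots, 0.15 * fs[2], 0.85 * fs[2]))
    } else NULL

    # hotspot area fraction by grid integration (for the truth record)
    gx <- seq(0, fs[1], length.out = 201)
    gy <- seq(0, fs[2], length.out = 201)
    gg <- expand.grid(x = gx, y = gy)
    a_in <- mean(.in_hotspot(gg$x, gg$y, centers, cfg$hotspot_sigma))

    place <- function(n, multiplier) {
      # rejection sampling against density 1 + (m - 1) * inside
      out_x <- numeric(0); out_y <- numeric(0)
      mmax <- max(multiplier, 1)
      while (length(out_x) < n) {
        need <- n - length(out_x)
        m <- ceiling(need * mmax * 1.3) + 10
        px <- stats::runif(m, 0, fs[1]); py <- stats::runif(m, 0, fs[2])
        w <- 1 + (multiplier - 1) * .in_hotspot(px, py, centers,
                                                cfg$hotspot_sigma)
        keep <- stats::runif(m) < w / mmax
        out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
      }
      cbind(out_x[seq_len(n)], out_y[seq_len(n)])
    }

    tum <- place(cfg$n_tumor_cells, 1)
    types <- names(cfg$cell_type_proportions)
    n_per_type <- stats::rmultinom(1, cfg$n_stromal_cells,
                                   cfg$cell_type_proportions)[, 1]
    str_xy <- NULL; str_type <- character(0)
    for (i in seq_along(types)) {
      if (n_per_type[i] == 0) next
      str_xy <- rbind(str_xy, place(n_per_type[i],
                                    cfg$hotspot_multiplier[[types[i]]]))
      str_type <- c(str_type, rep(types[i], n_per_type[i]))
    }
    n_art <- round(cfg$artifact_fraction *
                     (cfg$n_tumor_cells + cfg$n_stromal_cells))
    art <- if (n_art > 0) place(n_art, 1) else NULL

    x <- c(tum[, 1], if (!is.null(str_xy)) str_xy[, 1], if (n_art) art[, 1])
    y <- c(tum[, 2], if (!is.null(str_xy)) str_xy[, 2], if (n_art) art[, 2])
    compartment <- c(rep("tumor", cfg$n_tumor_cells),
                     rep("stroma", length(str_type)),
                     rep("artifact", n_art))
    cell_type <- c(rep("Tumor", cfg$n_tumor_cells), str_type,
                   rep(NA_character_, n_art))
    n_cells <- length(x)
    af <- stats::runif(n_cells, 1, 3)
    cells <- data.frame(
      cell_id = sprintf("c%05d", seq_len(n_cells)),
      x = x, y = y,
      compartment = compartment,
      cell_type = cell_type,
      cgas_intensity = af * stats::rlnorm(n_cells, log(4), 0.4),
      sting_intensity = af * stats::rlnorm(n_cells, log(3), 0.4),
      autofluorescence = af,
      stringsAsFactors = FALSE)

    # micronuclei per tumor/stromal cell
    draw_foci <- function(idx, rates, compart) {
      n_mn <- stats::rpois(length(idx), rates)
      parent <- rep(idx, n_mn)
      if (!length(parent)) return(NULL)
      data.frame(x = cells$x[parent] + stats::rnorm(length(parent), 0, 3),
                 y = cells$y[parent] + stats::rnorm(length(parent), 0, 3),
                 compartment = compart, stringsAsFactors = FALSE)
    }
    tum_idx <- which(cells$compartment == "tumor")
    tum_in <- .in_hotspot(cells$x[tum_idx], cells$y[tum_idx], centers,
                          cfg$hotspot_sigma)
    tum_rate <- ifelse(tum_in, cfg$mn_rate_hotspot, cfg$mn_rate_background)
    foci <- rbind(draw_foci(tum_idx, tum_rate, "tumor"),
                  draw_foci(which(cells$compartment == "stroma"),
                            cfg$mn_rate_stromal, "stroma"))
    if (is.null(foci))
      foci <- data.frame(x = numeric(0), y = numeric(0),
                         compartment = character(0), stringsAsFactors = FALSE)
    n_f <- nrow(foci)
    # areas: in-range core plus a configured fraction of out-of-range outliers
    area <- stats::runif(n_f, 0.5, 6)
    n_out <- round(cfg$frac_area_outliers * n_f)
    if (n_out > 0) {
      out_idx <- sample.int(n_f, n_out)
      small <- out_idx[seq_len(floor(n_out / 2))]
      big <- setdiff(out_idx, small)
      area[small] <- stats::runif(length(small), 0.05, 0.2)
      area[big] <- stats::runif(length(big), 8, 12)
    }
    foci <- data.frame(focus_id = sprintf("f%05d", seq_len(n_f)),
                       x = foci$x, y = foci$y, area = area,
                       cgas_intensity = stats::rlnorm(n_f, log(30), 0.3),
                       compartment = foci$compartment,
                       stringsAsFactors = FALSE)

    # expected fold enrichment per type from the density model:
    # P(inside | type t) = m_t * a_in / (m_t * a_in + (1 - a_in))
    mult_all <- c(Tumor = 1, cfg$hotspot_multiplier)
    prop_all <- c(Tumor = cfg$n_tumor_cells,
                  cfg$cell_type_proportions * cfg$n_stromal_cells)
    prop_all <- prop_all / sum(prop_all)
    w_in <- mult_all * a_in / (mult_all * a_in + (1 - a_in))
    p_in <- prop_all * w_in / sum(prop_all * w_in)
    p_out <- prop_all * (1 - w_in) / sum(prop_all * (1 - w_in))
    truth <- list(
      hotspot_centers = centers,
      hotspot_area_fraction = a_in,
      expected_fold_enrichment = stats::setNames(p_in / p_out,
                                                 names(mult_all)),
      tumor_cell_in_hotspot = tum_in,
      mn_rate_background = cfg$mn_rate_background,
      mn_rate_hotspot = cfg$mn_rate_hotspot,
      config = cfg)
    list(cells = cells, foci = foci, truth = truth)
  })
}

#' Configuration for the isogenic clone expression simulator
#'
#' Emulates an isogenic cell-line panel with genotypes of increasing
#' micronucleus (MN) burden, multiple independent clones per genotype and
#' repeated experimental batches, where a fraction of genes scale linearly
#' (on the log2 scale) with MN burden.
#'
#' @param n_genes Number of genes.
#' @param genotypes Data frame with columns \code{genotype}, \code{mn_burden}
#'   (MN per 100 cells) and \code{n_clones}. The default mirrors a founder
#'   line plus three engineered genotypes of escalating instability with
#'   three clones each.
#' @param n_batches Biological replicate batches.
#' @param frac_cin_genes Fraction of genes with a nonzero MN slope.
#' @param slope_scale Typical magnitude of true slopes (log2 units per MN%).
#'   CIN-gene slopes are drawn uniformly in \code{[0.5, 1.5] * slope_scale}
#'   with random sign.
#' @param clone_sd,batch_sd,resid_sd Standard deviations of the per-gene
#'   clone random intercept, batch-within-clone random intercept and residual
#'   noise (log2 units).
#' @param nb_dispersion Negative-binomial dispersion for count generation
#'   (scalar or per-gene vector).
#' @param baseline_log2_range Range of baseline log2 mean expression from
#'   which per-gene baselines are drawn uniformly.
#' @param seed Integer seed.
#' @return A list of class \code{expression_sim_config}.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  genotypes = data.frame(
                                    genotype = c("Cas9", "p53KO",
                                                 "p53p16DKO", "p53KOdnMCAK"),
                                    mn_burden = c(2, 5, 8, 12),
                                    n_clones = c(1, 3, 3, 3)),
                                  n_batches = 3,
                                  frac_cin_genes = 0.10,
                                  slope_scale = 0.08,
                                  clone_sd = 0.15,
                                  batch_sd = 0.10,
                                  resid_sd = 0.25,
                                  nb_dispersion = 0.05,
                                  baseline_log2_range = c(4, 10),
                                  seed = 1L) {
  stopifnot(is.data.frame(genotypes),
            all(c("genotype", "mn_burden", "n_clones") %in% names(genotypes)))
  if (frac_cin_genes < 0 || frac_cin_genes > 1)
    stop("frac_cin_genes must be in [0, 1]")
  for (nm in c("clone_sd", "batch_sd", "resid_sd"))
    .check_scalar(get(nm), nm, 0)
  if (any(nb_dispersion <= 0)) stop("nb_dispersion must be > 0")
  structure(list(n_genes = n_genes, genotypes = genotypes,
                 n_batches = n_batches, frac_cin_genes = frac_cin_genes,
                 slope_scale = slope_scale, clone_sd = clone_sd,
                 batch_sd = batch_sd, resid_sd = resid_sd,
                 nb_dispersion = nb_dispersion,
                 baseline_log2_range = baseline_log2_range, seed = seed),
            class = "expression_sim_config")
}

#' Simulate isogenic-panel RNA-seq counts scaling with MN burden
#'
#' Per-gene log2 mean expression is
#' \code{baseline + slope * MN + clone + batch} with Gaussian random
#' intercepts (the batch effect is shared by all clones measured in that
#' experimental session) and residual noise; counts are drawn
#' negative-binomial around the resulting mean, with modest library-size
#' variation between samples. Sample metadata carries the clone, batch and
#' clone-level mean MN burden used downstream by the mixed-model discovery
#' step.
#'
#' @param cfg An \code{\link{expression_sim_config}}.
#' @return List with \code{counts} (genes x samples integer matrix),
#'   \code{meta} (sample metadata) and \code{truth} (per-gene true slope and
#'   CIN flag).
#' @export
make_isogenic_counts <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  if (sum(cfg$genotypes$n_clones) < 2)
    warning("fewer than 2 clones overall: clone random effect unidentifiable")
  with_seed(cfg$seed, {
    g <- cfg$genotypes
    clones <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      data.frame(genotype = g$genotype[i],
                 clone = paste0(g$genotype[i], "_cl", seq_len(g$n_clones[i])),
                 mn = g$mn_burden[i], stringsAsFactors = FALSE)
    }))
    meta <- do.call(rbind, lapply(seq_len(cfg$n_batches), function(b) {
      transform(clones, batch = paste0("b", b))
    }))
    meta$sample <- paste0(meta$clone, "_", meta$batch)
    rownames(meta) <- meta$sample
    n_s <- nrow(meta)

    n_cin <- round(cfg$frac_cin_genes * cfg$n_genes)
    is_cin <- c(rep(TRUE, n_cin), rep(FALSE, cfg$n_genes - n_cin))
    slope <- numeric(cfg$n_genes)
    if (n_cin > 0)
      slope[is_cin] <- sample(c(-1, 1), n_cin, replace = TRUE) *
        stats::runif(n_cin, 0.5, 1.5) * cfg$slope_scale
    baseline <- stats::runif(cfg$n_genes, cfg$baseline_log2_range[1],
                             cfg$baseline_log2_range[2])

    clone_eff <- matrix(stats::rnorm(cfg$n_genes * nrow(clones),
                                     0, cfg$clone_sd),
                        cfg$n_genes, nrow(clones),
                        dimnames = list(NULL, clones$clone))
    batches <- unique(meta$batch)
    batch_eff <- matrix(stats::rnorm(cfg$n_genes * length(batches),
                                     0, cfg$batch_sd),
                        cfg$n_genes, length(batches),
                        dimnames = list(NULL, batches))

    lib <- stats::rlnorm(n_s, 0, 0.15)
    disp <- rep_len(cfg$nb_dispersion, cfg$n_genes)
    counts <- matrix(0L, cfg$n_genes, n_s,
                     dimnames = list(sprintf("gene%04d", seq_len(cfg$n_genes)),
                                     meta$sample))
    for (j in seq_len(n_s)) {
      lmu <- baseline + slope * meta$mn[j] +
        clone_eff[, meta$clone[j]] +
        batch_eff[, meta$batch[j]] +
        stats::rnorm(cfg$n_genes, 0, cfg$resid_sd)
      mu <- 2^lmu * lib[j]
      counts[, j] <- stats::rnbinom(cfg$n_genes, mu = mu, size = 1 / disp)
    }
    truth <- data.frame(gene = rownames(counts), is_cin = is_cin,
                        true_slope = slope, stringsAsFactors = FALSE)
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Simulate a paired knockout RNA-seq experiment
#'
#' Generates counts for a 2x2 design (genotype Cas9 / cGAS_KO by treatment
#' DMSO / MPS1i) across paired batches. Genes in \code{induced_set} gain
#' \code{lfc} log2 units under MPS1i in Cas9 cells; genes in
#' \code{dependent_subset} have that induction multiplied by
#' \code{dependence_attenuation} in the knockout, emulating cGAS-dependent
#' induction. Batch effects are shared across the four conditions within a
#' batch, matching the paired analysis downstream.
#'
#' @param n_genes Number of genes.
#' @param induced_set Integer or character indices of MPS1i-induced genes.
#' @param dependent_subset Subset of \code{induced_set} whose induction is
#'   attenuated in the knockout.
#' @param lfc True induction (log2 fold change) in Cas9 cells.
#' @param dependence_attenuation Multiplier (< 1 for true dependence) on the
#'   induction lfc in knockout cells.
#' @param nb_dispersion NB dispersion (scalar or per-gene).
#' @param n_batches Paired batches (the reference design uses 3).
#' @param seed Integer seed.
#' @return List with \code{counts}, \code{meta} and \code{truth}.
#' @export
make_ko_experiment <- function(n_genes = 2000,
                               induced_set = seq_len(round(0.1 * n_genes)),
                               dependent_subset =
                                 induced_set[seq_len(floor(length(induced_set) / 2))],
                               lfc = 2,
                               dependence_attenuation = 0.25,
                               nb_dispersion = 0.05,
                               n_batches = 3,
                               seed = 1L) {
  genes <- sprintf("gene%04d", seq_len(n_genes))
  as_idx <- function(s) if (is.character(s)) match(s, genes) else as.integer(s)
  ind <- as_idx(induced_set); dep <- as_idx(dependent_subset)
  if (!all(dep %in% ind))
    stop("dependent_subset must be a subset of induced_set")
  if (any(nb_dispersion <= 0)) stop("nb_dispersion must be > 0")
  with_seed(seed, {
    meta <- expand.grid(genotype = c("Cas9", "cGAS_KO"),
                        treatment = c("DMSO", "MPS1i"),
                        batch = paste0("b", seq_len(n_batches)),
                        stringsAsFactors = FALSE)
    meta$sample <- with(meta, paste(genotype, treatment, batch, sep = "_"))
    rownames(meta) <- meta$sample
    n_s <- nrow(meta)

    baseline <- stats::runif(n_genes, 4, 10)
    true_lfc_cas9 <- numeric(n_genes); true_lfc_cas9[ind] <- lfc
    true_lfc_ko <- true_lfc_cas9
    true_lfc_ko[dep] <- lfc * dependence_attenuation

    batch_eff <- matrix(stats::rnorm(n_genes * n_batches, 0, 0.1),
                        n_genes, n_batches)
    lib <- stats::rlnorm(n_s, 0, 0.1)
    disp <- rep_len(nb_dispersion, n_genes)
    counts <- matrix(0L, n_genes, n_s, dimnames = list(genes, meta$sample))
    for (j in seq_len(n_s)) {
      b <- as.integer(sub("b", "", meta$batch[j]))
      ind_lfc <- if (meta$treatment[j] == "MPS1i") {
        if (meta$genotype[j] == "Cas9") true_lfc_cas9 else true_lfc_ko
      } else 0
      mu <- 2^(baseline + batch_eff[, b] + ind_lfc) * lib[j]
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / disp)
    }
    truly_dependent <- logical(n_genes)
    truly_dependent[dep] <- dependence_attenuation < 1 & lfc != 0
    truth <- data.frame(gene = genes,
                        induced = seq_len(n_genes) %in% ind,
                        dependent = truly_dependent,
                        true_lfc_cas9 = true_lfc_cas9,
                        true_lfc_ko = true_lfc_ko,
                        stringsAsFactors = FALSE)
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Simulate binned single-cell karyotypes
#'
#' Each cell starts at the base ploidy over all bins; mis-segregation events
#' (whole-chromosome or contiguous segmental gains/losses of one copy) are
#' applied per cell at a Poisson rate. Bins are grouped into 22 chromosomes
#' of unequal length.
#'
#' @param n_cells Number of cells (libraries).
#' @param n_bins Number of genomic bins.
#' @param bin_sizes Bin sizes in bp (scalar or vector of length n_bins).
#' @param base_ploidy Starting copy number for every bin.
#' @param missegregation_rate Expected events per cell.
#' @param frac_whole_chrom Fraction of events affecting a whole chromosome
#'   (the remainder are contiguous segmental events).
#' @param reads_per_copy If non-NULL, per-bin read counts are drawn
#'   Poisson(reads_per_copy * copy number) to support library QC.
#' @param seed Integer seed.
#' @return List with \code{cn} (a \code{\link{cn_matrix}}) and \code{truth}
#'   (the exact event log).
#' @export
make_karyotypes <- function(n_cells = 24, n_bins = 220, bin_sizes = 1e6,
                            base_ploidy = 2, missegregation_rate = 0.5,
                            frac_whole_chrom = 0.6, reads_per_copy = 30,
                            seed = 1L) {
  stopifnot(n_cells >= 1, n_bins >= 22, base_ploidy >= 0)
  .check_scalar(missegregation_rate, "missegregation_rate", 0)
  with_seed(seed, {
    # chromosome lengths roughly decreasing, in bins
    w <- rev(seq_len(22)) + 4
    per_chrom <- pmax(1, round(n_bins * w / sum(w)))
    while (sum(per_chrom) != n_bins) {
      i <- which.max(per_chrom)
      per_chrom[i] <- per_chrom[i] + sign(n_bins - sum(per_chrom))
    }
    chrom <- rep(paste0("chr", seq_len(22)), per_chrom)
    size <- rep_len(bin_sizes, n_bins)
    start <- unlist(lapply(split(size, factor(chrom, unique(chrom))),
                           function(s) cumsum(c(0, s[-length(s)]))),
                    use.names = FALSE) + 1
    bins <- data.frame(chrom = chrom, start = start,
                       end = start + size - 1, size = size,
                       stringsAsFactors = FALSE)

    cn <- matrix(as.integer(base_ploidy), n_cells, n_bins,
                 dimnames = list(sprintf("cell%03d", seq_len(n_cells)), NULL))
    events <- list()
    for (i in seq_len(n_cells)) {
      n_ev <- stats::rpois(1, missegregation_rate)
      for (e in seq_len(n_ev)) {
        ch <- sample(unique(chrom), 1)
        idx <- which(chrom == ch)
        whole <- stats::runif(1) < frac_whole_chrom
        if (!whole && length(idx) > 1) {
          a <- sample(seq_along(idx), 1)
          b <- min(length(idx), a + sample(1:max(1, length(idx) %/% 2), 1))
          idx <- idx[a:b]
        }
        delta <- sample(c(-1L, 1L), 1)
        cn[i, idx] <- pmax(0L, cn[i, idx] + delta)
        events[[length(events) + 1L]] <-
          data.frame(cell = i, chrom = ch, whole = whole, delta = delta,
                     first_bin = idx[1], last_bin = idx[length(idx)])
      }
    }
    reads <- if (!is.null(reads_per_copy)) {
      matrix(stats::rpois(length(cn), reads_per_copy * as.vector(cn)),
             n_cells, n_bins, dimnames = dimnames(cn))
    } else NULL
    obj <- cn_matrix(cn, bins, expected = base_ploidy, reads = reads)
    truth <- list(events = if (length(events)) do.call(rbind, events) else NULL,
                  base_ploidy = base_ploidy, cn = cn)
    list(cn = obj, truth = truth)
  })
}

#' Simulate a patient cohort linking CIN, myeloid skew and survival
#'
#' MN scores are gamma-distributed; a myeloid infiltration feature rises
#' linearly with MN burden at a response-class-specific slope; survival times
#' are exponential with log-hazard linear in the standardized CIN score and
#' standardized myeloid:lymphoid skew; independent exponential censoring is
#' tuned to the requested rate. Orthogonal CIN scores (a transcriptional
#' surrogate and an aneuploidy-like score) are generated as noisy linear
#' functions of the MN score so that covariate-adjusted agreement can be
#' recovered.
#'
#' @param n_tumors Cohort size.
#' @param mn_distribution List with gamma \code{shape} and \code{scale} for
#'   the MN score (MN per 100 cells).
#' @param effect_mn_on_myeloid Named vector \code{c(R = , NR = )}: slope of
#'   the myeloid feature on MN score per response class.
#' @param hazard_coefficients Named vector \code{c(cin = , skew = )}:
#'   log-hazard coefficients of the standardized CIN score and skew.
#' @param censoring_rate Target fraction of censored subjects.
#' @param seed Integer seed.
#' @return List with \code{cohort} (data frame) and \code{truth}.
#' @export
make_cohort <- function(n_tumors = 200,
                        mn_distribution = list(shape = 2, scale = 3),
                        effect_mn_on_myeloid = c(R = 0.2, NR = 0.7),
                        hazard_coefficients = c(cin = 0.5, skew = 0.4),
                        censoring_rate = 0.3,
                        seed = 1L) {
  stopifnot(n_tumors >= 4, censoring_rate >= 0, censoring_rate < 1)
  with_seed(seed, {
    mn <- stats::rgamma(n_tumors, shape = mn_distribution$shape,
                        scale = mn_distribution$scale)
    response <- sample(c("R", "NR", "other"), n_tumors, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2))
    trg <- ifelse(response == "R", sample(1:2, n_tumors, TRUE),
                  ifelse(response == "NR", sample(4:5, n_tumors, TRUE), 3L))
    slope_cl <- ifelse(response == "NR", effect_mn_on_myeloid[["NR"]],
                       effect_mn_on_myeloid[["R"]])
    myeloid <- 5 + slope_cl * mn + stats::rnorm(n_tumors, 0, 1)
    lymphoid <- 8 - 0.05 * mn + stats::rnorm(n_tumors, 0, 1)
    skew <- myeloid - lymphoid

    cin_mn <- as.numeric(scale(mn)) + stats::rnorm(n_tumors, 0, 0.3)
    purity <- stats::rbeta(n_tumors, 5, 2)
    leukocyte <- stats::rbeta(n_tumors, 2, 5)
    cin70 <- 1.5 * cin_mn + 0.8 * leukocyte + stats::rnorm(n_tumors, 0, 0.5)
    aneuploidy <- 1.0 * cin_mn - 0.5 * (1 - purity) +
      stats::rnorm(n_tumors, 0, 0.5)
    cgas_sting <- stats::rnorm(n_tumors)

    lp <- hazard_coefficients[["cin"]] * as.numeric(scale(mn)) +
      hazard_coefficients[["skew"]] * as.numeric(scale(skew))
    rate <- 0.05 * exp(lp)
    t_event <- stats::rexp(n_tumors, rate)
    if (censoring_rate > 0) {
      c_rate <- mean(rate) * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(n_tumors, c_rate)
    } else t_cens <- rep(Inf, n_tumors)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    cohort <- data.frame(
      tumor_id = sprintf("t%03d", seq_len(n_tumors)),
      mn_score = mn, response = response, trg = trg,
      myeloid = myeloid, lymphoid = lymphoid, skew = skew,
      cin_mn_score = cin_mn, cin70_score = cin70,
      aneuploidy_score = aneuploidy, cgas_sting_score = cgas_sting,
      purity = purity, leukocyte_fraction = leukocyte,
      time = time, event = event, stringsAsFactors = FALSE)
    truth <- list(effect_mn_on_myeloid = effect_mn_on_myeloid,
                  slope_difference = effect_mn_on_myeloid[["NR"]] -
                    effect_mn_on_myeloid[["R"]],
                  hazard_coefficients = hazard_coefficients,
                  linear_predictor = lp)
    list(cohort = cohort, truth = truth)
  })
}
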