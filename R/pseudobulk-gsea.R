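# Pseudobulk aggregation of single-nucleus counts, per-gene correlation with
# tumor MN scores, and preranked GSEA with a permutation null, including
# second-pass meta-enrichment of pathway groups.

#' Aggregate single-cell counts to compartment-level pseudobulk
#'
#' Sums raw counts over cells within each (compartment, sample) group, then
#' normalizes across samples within each compartment by median-of-ratios
#' size factors.
#'
#' @param cell_counts Genes x cells count matrix.
#' @param cell_compartment,cell_sample Character/factor vectors over cells.
#' @return List: \code{counts} (genes x groups summed counts),
#'   \code{normalized} (size-factor normalized), \code{compartment} and
#'   \code{sample} (group annotations, aligned with columns).
#' @export
pseudobulk_aggregate <- function(cell_counts, cell_compartment, cell_sample) {
  cell_counts <- as.matrix(cell_counts)
  stopifnot(length(cell_compartment) == ncol(cell_counts),
            length(cell_sample) == ncol(cell_counts))
  grp <- paste(cell_compartment, cell_sample, sep = "||")
  agg <- t(rowsum(t(cell_counts), grp))
  comp <- sub("\\|\\|.*$", "", colnames(agg))
  samp <- sub("^.*\\|\\|", "", colnames(agg))
  norm <- agg
  for (cc in unique(comp)) {
    j <- comp == cc
    if (sum(j) > 1) {
      sf <- size_factors(agg[, j, drop = FALSE])
      norm[, j] <- sweep(agg[, j, drop = FALSE], 2, sf, "/")
    }
  }
  list(counts = agg, normalized = norm, compartment = comp, sample = samp)
}

#' Correlate gene expression with tumor MN scores
#'
#' Pearson correlation of each gene's normalized expression with per-sample
#' MN scores; constant genes are reported with NA.
#'
#' @param expr Genes x samples normalized expression matrix.
#' @param mn_scores Numeric vector aligned with columns (>= 3 samples).
#' @return Data frame: gene, r_p, p_value.
#' @export
correlate_with_mn <- function(expr, mn_scores) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  stopifnot(length(mn_scores) == n)
  if (n < 3) stop("at least 3 samples are required")
  sds <- apply(expr, 1, stats::sd)
  r <- suppressWarnings(as.numeric(stats::cor(t(expr), mn_scores)))
  r[sds == 0 | stats::sd(mn_scores) == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(gene = rownames(expr), r_p = r, p_value = p,
             stringsAsFactors = FALSE)
}

#' Signed rank metric from differential-expression output
#'
#' The standard preranked metric -log10(adjusted p) * sign(log2FC).
#'
#' @param padj Adjusted p-values.
#' @param log2fc Log2 fold changes.
#' @param floor Smallest p used, to keep the metric finite (default 1e-300).
#' @return Numeric metric vector.
#' @export
dge_rank_metric <- function(padj, log2fc, floor = 1e-300) {
  -log10(pmax(padj, floor)) * sign(log2fc)
}

# Weighted Kolmogorov-Smirnov enrichment score from the positions of set
# members in the ranked list. absw: |metric| over the full ranked list;
# pos: sorted member positions. Extremes of the running sum occur at member
# positions (after the hit) or immediately before them.
.gsea_es <- function(absw, pos, n) {
  k <- length(pos)
  # a set covering the whole list has an empty out-set: the running sum is
  # the in-set CDF itself, with extremum 1 at the end
  if (k == n) return(1)
  w <- absw[pos]
  tot <- sum(w)
  if (tot == 0) w <- rep(1, k) else w <- w
  cw <- cumsum(w) / sum(w)
  miss_at <- (pos - seq_len(k)) / (n - k)
  top <- cw - miss_at                      # running sum just after hit i
  bottom <- c(0, cw[-k]) - (pos - 1 - (seq_len(k) - 1)) / (n - k)
  hi <- max(top); lo <- min(bottom)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment with weight
#' |metric|, a gene-label permutation null, normalized enrichment scores
#' (ES divided by the mean |null ES| of the same sign) and FDR q-values by
#' the standard sign-stratified pooling of null and observed NES. Ties in
#' the metric are broken by gene name so results are deterministic.
#'
#' @param ranked Named numeric vector: gene -> rank metric (finite values
#'   only).
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param min_size Sets with fewer than this many genes in the ranked list
#'   are skipped (default 3).
#' @return Data frame: pathway, size, es, nes, p_value, fdr_q.
#' @export
preranked_gsea <- function(ranked, gene_sets, n_perm = 1000, seed = 1L,
                           min_size = 3) {
  stopifnot(!is.null(names(ranked)), all(is.finite(ranked)))
  ord <- order(-ranked, names(ranked))
  genes <- names(ranked)[ord]
  absw <- abs(ranked[ord])
  n <- length(genes)
  sets <- lapply(gene_sets, function(s) which(genes %in% s))
  keep <- vapply(sets, length, integer(1)) >= min_size
  if (!any(keep))
    return(data.frame(pathway = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_value = numeric(0), fdr_q = numeric(0)))
  sets <- sets[keep]
  sizes <- vapply(sets, length, integer(1))

  res <- with_seed(seed, {
    es_obs <- vapply(sets, function(p) .gsea_es(absw, sort(p), n),
                     numeric(1))
    # one permutation null per distinct set size
    null_by_size <- lapply(unique(sizes), function(k)
      vapply(seq_len(n_perm), function(i)
        .gsea_es(absw, sort(sample.int(n, k)), n), numeric(1)))
    names(null_by_size) <- as.character(unique(sizes))

    nes_obs <- numeric(length(sets)); p_val <- numeric(length(sets))
    nes_null <- vector("list", length(sets))
    for (i in seq_along(sets)) {
      nul <- null_by_size[[as.character(sizes[i])]]
      same <- if (es_obs[i] >= 0) nul[nul >= 0] else nul[nul < 0]
      denom <- mean(abs(same))
      if (!length(same) || denom == 0) {
        nes_obs[i] <- NA_real_; p_val[i] <- NA_real_
        nes_null[[i]] <- numeric(0)
        next
      }
      nes_obs[i] <- es_obs[i] / denom
      p_val[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
      pos_m <- mean(abs(nul[nul >= 0]))
      neg_m <- mean(abs(nul[nul < 0]))
      nes_null[[i]] <- ifelse(nul >= 0,
                              nul / ifelse(is.finite(pos_m) & pos_m > 0,
                                           pos_m, NA_real_),
                              nul / ifelse(is.finite(neg_m) & neg_m > 0,
                                           neg_m, NA_real_))
    }
    pooled_null <- unlist(nes_null)
    fdr <- vapply(seq_along(sets), function(i) {
      nes <- nes_obs[i]
      if (is.na(nes)) return(NA_real_)
      if (nes >= 0) {
        num <- mean(pooled_null[pooled_null >= 0] >= nes, na.rm = TRUE)
        den <- mean(nes_obs[nes_obs >= 0] >= nes, na.rm = TRUE)
      } else {
        num <- mean(pooled_null[pooled_null < 0] <= nes, na.rm = TRUE)
        den <- mean(nes_obs[nes_obs < 0] <= nes, na.rm = TRUE)
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
    data.frame(pathway = names(sets), size = unname(sizes),
               es = unname(es_obs), nes = nes_obs, p_value = p_val,
               fdr_q = fdr, stringsAsFactors = FALSE, row.names = NULL)
  })
  res
}

#' Meta-enrichment of pathway groups over first-pass GSEA output
#'
#' Treats gene sets as items ranked by their first-pass normalized
#' enrichment score and runs preranked GSEA of group membership over that
#' ranking, asking whether a named family of pathways (e.g. interferon
#' response) is concentrated at either end of the enrichment spectrum.
#'
#' @param gsea_results Data frame from \code{\link{preranked_gsea}} (needs
#'   \code{pathway} and \code{nes}).
#' @param group_lists Named list: group -> character vector of pathway
#'   names.
#' @param n_perm,seed,min_size Passed to \code{\link{preranked_gsea}}.
#' @return Data frame of group-level enrichment results.
#' @export
pathway_group_enrichment <- function(gsea_results, group_lists,
                                     n_perm = 1000, seed = 1L,
                                     min_size = 3) {
  ok <- is.finite(gsea_results$nes)
  ranked <- stats::setNames(gsea_results$nes[ok], gsea_results$pathway[ok])
  preranked_gsea(ranked, group_lists, n_perm = n_perm, seed = seed,
                 min_size = min_size)
}
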