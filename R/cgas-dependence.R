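# Classification of CIN/MPS1i-induced genes by cGAS dependence:
# negative-binomial differential expression in cGAS-proficient cells plus a
# paired per-batch fold-change test between genotypes.

#' Filter lowly expressed genes
#'
#' Keeps genes with a total read count of at least \code{min_total} across
#' all samples and nonzero counts in at least \code{min_expressed_samples}
#' samples.
#'
#' @param counts Genes x samples count matrix.
#' @param min_total Minimum total count (default 5).
#' @param min_expressed_samples Minimum number of samples with nonzero
#'   counts (default 4).
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_total = 5, min_expressed_samples = 4) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) >= min_total &
    rowSums(counts > 0) >= min_expressed_samples
  counts[keep, , drop = FALSE]
}

#' Negative-binomial differential expression (Wald test)
#'
#' Two-group differential expression with median-of-ratios size factors, a
#' per-gene NB GLM, a Wald test on the group coefficient and
#' Benjamini-Hochberg adjustment, via DESeq2.
#'
#' @param counts Genes x samples count matrix covering both groups.
#' @param condition Factor/character of length \code{ncol(counts)} with two
#'   levels.
#' @param ref_level Reference level (log2 fold changes are
#'   \code{other / ref_level}).
#' @return Data frame: \code{gene}, \code{base_mean}, \code{log2fc},
#'   \code{pvalue}, \code{padj}.
#' @export
differential_expression <- function(counts, condition, ref_level = NULL) {
  counts <- as.matrix(counts)
  condition <- factor(condition)
  stopifnot(length(condition) == ncol(counts), nlevels(condition) == 2)
  if (min(table(condition)) < 2)
    stop("at least 2 replicates per group are required")
  if (!is.null(ref_level)) condition <- stats::relevel(condition, ref_level)
  coldata <- S4Vectors::DataFrame(condition = condition)
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = counts,
                                        colData = coldata,
                                        design = ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds)
  data.frame(gene = rownames(res), base_mean = res$baseMean,
             log2fc = res$log2FoldChange, pvalue = res$pvalue,
             padj = res$padj, stringsAsFactors = FALSE)
}

#' Per-batch log2 fold changes (treatment vs control)
#'
#' Normalizes the supplied counts by median-of-ratios size factors, then for
#' each batch computes log2((treated + c) / (control + c)) per gene with
#' pseudocount c.
#'
#' @param counts Genes x samples count matrix (the samples to be compared;
#'   size factors are estimated on exactly these columns).
#' @param meta Data frame aligned with the columns, containing
#'   \code{treatment} and \code{batch}.
#' @param treated,control Treatment labels (defaults "MPS1i" and "DMSO").
#' @param pseudocount Added to normalized counts before the ratio
#'   (default 0.5).
#' @return Genes x batches matrix of log2 fold changes.
#' @export
per_batch_log2fc <- function(counts, meta, treated = "MPS1i",
                             control = "DMSO", pseudocount = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(nrow(meta) == ncol(counts),
            all(c("treatment", "batch") %in% names(meta)))
  norm <- sweep(counts, 2, size_factors(counts), "/")
  batches <- sort(unique(meta$batch))
  out <- sapply(batches, function(b) {
    it <- which(meta$batch == b & meta$treatment == treated)
    ic <- which(meta$batch == b & meta$treatment == control)
    if (length(it) < 1 || length(ic) < 1)
      stop("batch ", b, " is missing a treatment arm")
    log2((rowMeans(norm[, it, drop = FALSE]) + pseudocount) /
           (rowMeans(norm[, ic, drop = FALSE]) + pseudocount))
  })
  colnames(out) <- batches
  out
}

# Vectorized two-sided paired t-test across matrix rows (x vs y, paired by
# column). Returns p-values; NA where the differences are constant at 0 sd.
.paired_t_rows <- function(x, y) {
  d <- x - y
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[s == 0 & m == 0] <- 1
  p
}

#' Classify genes by cGAS dependence of their MPS1i response
#'
#' A gene is a cGAS-dependent induced gene when it is significantly
#' up-regulated by MPS1i in cGAS-proficient cells (BH-adjusted p <=
#' \code{padj_cut} and log2FC > 0) and its per-batch induction is
#' significantly reduced in the knockout (two-sided paired t-test across
#' batches, p <= \code{t_cut}, with mean lfc in proficient cells exceeding
#' the knockout mean). The suppressed class is the mirror image. Genes that
#' pass the differential-expression gate without a dependence signal are
#' "cGAS_independent_changed"; the rest are "unchanged".
#'
#' @param de_cas9 Differential-expression table from
#'   \code{\link{differential_expression}} on cGAS-proficient samples.
#' @param lfc_by_batch_cas9,lfc_by_batch_ko Genes x batches log2FC matrices
#'   from \code{\link{per_batch_log2fc}} (same genes, same batch order).
#' @param padj_cut Adjusted-p cutoff for the induction gate (default 0.01).
#' @param t_cut Paired-test p cutoff for the dependence gate (default 0.05).
#' @return Data frame: gene, class, lfc_cas9, padj_cas9, paired_t_p,
#'   mean_lfc_cas9, mean_lfc_ko.
#' @export
classify_cgas_dependence <- function(de_cas9, lfc_by_batch_cas9,
                                     lfc_by_batch_ko,
                                     padj_cut = 0.01, t_cut = 0.05) {
  genes <- de_cas9$gene
  stopifnot(identical(genes, rownames(lfc_by_batch_cas9)),
            identical(genes, rownames(lfc_by_batch_ko)),
            ncol(lfc_by_batch_cas9) == ncol(lfc_by_batch_ko))
  p_t <- .paired_t_rows(lfc_by_batch_cas9, lfc_by_batch_ko)
  m_cas9 <- rowMeans(lfc_by_batch_cas9)
  m_ko <- rowMeans(lfc_by_batch_ko)
  padj <- de_cas9$padj
  sig_up <- !is.na(padj) & padj <= padj_cut & de_cas9$log2fc > 0
  sig_dn <- !is.na(padj) & padj <= padj_cut & de_cas9$log2fc < 0
  dep <- !is.na(p_t) & p_t <= t_cut
  cls <- rep("unchanged", length(genes))
  cls[sig_up | sig_dn] <- "cGAS_independent_changed"
  cls[sig_up & dep & m_cas9 > m_ko] <- "cGAS_dependent_induced"
  cls[sig_dn & dep & m_cas9 < m_ko] <- "cGAS_dependent_suppressed"
  data.frame(gene = genes, class = cls, lfc_cas9 = de_cas9$log2fc,
             padj_cas9 = padj, paired_t_p = p_t,
             mean_lfc_cas9 = m_cas9, mean_lfc_ko = m_ko,
             stringsAsFactors = FALSE)
}

#' Consensus cGAS-dependent induced genes across cell lines
#'
#' @param calls_by_line Named list of classification tables from
#'   \code{\link{classify_cgas_dependence}}, one per cell line.
#' @param class Dependence class to intersect (default the induced class).
#' @return Character vector: genes in the class in every line.
#' @export
consensus_hits <- function(calls_by_line,
                           class = "cGAS_dependent_induced") {
  stopifnot(length(calls_by_line) >= 1)
  sets <- lapply(calls_by_line, function(d) d$gene[d$class == class])
  Reduce(intersect, sets)
}

#' End-to-end dependence calls for one cell line
#'
#' Convenience pipeline: gene filtering, MPS1i-vs-DMSO differential
#' expression in cGAS-proficient samples, per-batch fold changes in both
#' genotypes, and classification.
#'
#' @param counts Genes x samples count matrix for the 2x2 design.
#' @param meta Sample metadata aligned with columns: \code{genotype}
#'   (\code{"Cas9"} / \code{"cGAS_KO"}), \code{treatment}
#'   (\code{"DMSO"} / \code{"MPS1i"}), \code{batch}.
#' @param padj_cut,t_cut Cutoffs passed to
#'   \code{\link{classify_cgas_dependence}}.
#' @return The classification table.
#' @export
call_cgas_dependence <- function(counts, meta, padj_cut = 0.01,
                                 t_cut = 0.05) {
  counts <- filter_genes(counts)
  cas9 <- meta$genotype == "Cas9"
  de <- differential_expression(counts[, cas9, drop = FALSE],
                                meta$treatment[cas9], ref_level = "DMSO")
  lfc_cas9 <- per_batch_log2fc(counts[, cas9, drop = FALSE],
                               meta[cas9, , drop = FALSE])
  ko <- meta$genotype == "cGAS_KO"
  lfc_ko <- per_batch_log2fc(counts[, ko, drop = FALSE],
                             meta[ko, , drop = FALSE])
  classify_cgas_dependence(de, lfc_cas9, lfc_ko,
                           padj_cut = padj_cut, t_cut = t_cut)
}
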