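# Per-gene mixed-effects association of expression with micronucleus burden,
# derivation of the CIN-MN signature, single-sample signature scoring, and
# compartment marker signature selection.

#' Filter and normalize an isogenic-panel count matrix
#'
#' Keeps genes with a total count of at least \code{min_total} across all
#' samples and nonzero expression in at least \code{min_expressed_samples}
#' samples, then applies median-of-ratios size factors and log2(x + 1) as a
#' variance-stabilizing transform.
#'
#' @param counts Genes x samples count matrix.
#' @param min_total Total-count threshold (default 50).
#' @param min_expressed_samples Nonzero-sample threshold (default 4).
#' @return Matrix of normalized log2 expression values.
#' @export
filter_and_normalize <- function(counts, min_total = 50,
                                 min_expressed_samples = 4) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) >= min_total &
    rowSums(counts > 0) >= min_expressed_samples
  normalize_log2(counts[keep, , drop = FALSE])
}

#' Mixed-effects association of one gene with MN burden
#'
#' Fits expression ~ MN burden with crossed random intercepts for clone and
#' experimental batch (\code{(1 | clone) + (1 | batch)}), by REML: clones
#' carry the line-to-line variation the MN effect must be separated from,
#' and batches are shared experimental sessions across clones. With one
#' sample per clone and batch, a batch-within-clone term would coincide
#' with the residual, so the crossed structure is the identifiable reading
#' of "clone and batch random effects". The slope is the fixed MN effect;
#' the p-value is the ANOVA F-test of that effect with Satterthwaite
#' degrees of freedom. If the mixed fit fails, an ordinary least-squares
#' fit is used and flagged.
#'
#' @param expression Numeric vector of (variance-stabilized) expression.
#' @param mn Clone-level mean MN burden per sample (MN per 100 cells).
#' @param clone,batch Grouping factors per sample.
#' @return One-row data frame: slope, p_value, clone_var, batch_var,
#'   resid_var, singular, fallback_ols.
#' @export
fit_mn_lmm <- function(expression, mn, clone, batch) {
  stopifnot(length(mn) == length(expression),
            length(clone) == length(expression),
            length(batch) == length(expression))
  if (length(unique(clone)) < 2 || length(unique(batch)) < 2)
    stop("at least 2 clones and 2 batches are required")
  d <- data.frame(y = expression, mn = mn, clone = factor(clone),
                  batch = factor(batch))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ mn + (1 | clone) + (1 | batch), data = d))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    an <- tryCatch(suppressMessages(stats::anova(fit)),
                   error = function(e) NULL)
    if (!is.null(an) && "mn" %in% rownames(an)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      getv <- function(g) {
        v <- vc$vcov[vc$grp == g]
        if (length(v)) v[1] else NA_real_
      }
      return(data.frame(slope = unname(lme4::fixef(fit)["mn"]),
                        p_value = an["mn", "Pr(>F)"],
                        clone_var = getv("clone"),
                        batch_var = getv("batch"),
                        resid_var = getv("Residual"),
                        singular = lme4::isSingular(fit),
                        fallback_ols = FALSE))
    }
  }
  ols <- stats::lm(y ~ mn, data = d)
  sm <- summary(ols)$coefficients
  data.frame(slope = sm["mn", "Estimate"], p_value = sm["mn", "Pr(>|t|)"],
             clone_var = NA_real_, batch_var = NA_real_,
             resid_var = summary(ols)$sigma^2,
             singular = NA, fallback_ols = TRUE)
}

#' Per-gene MN association over a whole expression matrix
#'
#' Applies \code{\link{fit_mn_lmm}} to every row of a normalized expression
#' matrix.
#'
#' @param expr Genes x samples normalized expression matrix.
#' @param meta Data frame aligned with columns, containing \code{mn},
#'   \code{clone} and \code{batch}.
#' @return Data frame with one row per gene: gene, slope, p_value, variance
#'   components and fit flags.
#' @export
fit_mn_lmm_all <- function(expr, meta) {
  stopifnot(ncol(expr) == nrow(meta),
            all(c("mn", "clone", "batch") %in% names(meta)))
  res <- do.call(rbind, lapply(seq_len(nrow(expr)), function(i)
    fit_mn_lmm(expr[i, ], meta$mn, meta$clone, meta$batch)))
  cbind(data.frame(gene = rownames(expr), stringsAsFactors = FALSE), res)
}

#' Derive the CIN-MN signature
#'
#' Restricts MN associations to positive slopes, ranks by ascending p-value
#' (ties broken by larger slope) and takes the top \code{k} genes.
#'
#' @param associations Data frame from \code{\link{fit_mn_lmm_all}}.
#' @param k Signature size (default 70).
#' @return Character vector of gene names (shorter than \code{k}, with a
#'   warning, when fewer positive-slope genes exist).
#' @export
derive_cin_mn_signature <- function(associations, k = 70) {
  pos <- associations[associations$slope > 0 & !is.na(associations$p_value), ,
                      drop = FALSE]
  pos <- pos[order(pos$p_value, -pos$slope), , drop = FALSE]
  if (nrow(pos) < k)
    warning("only ", nrow(pos), " positive-slope genes available (k = ",
            k, ")")
  utils::head(pos$gene, k)
}

# Single-sample enrichment score for one sample's expression vector.
.ssgsea_one <- function(x, in_set, alpha) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  in_ord <- in_set[ord]
  w <- r[ord]^alpha * in_ord
  cdf_in <- cumsum(w) / sum(w)
  cdf_out <- cumsum(!in_ord) / (n - sum(in_set))
  sum(cdf_in - cdf_out)
}

#' Single-sample GSEA signature scores
#'
#' Rank-based per-sample scoring: genes are ranked by expression within each
#' sample; the score is the sum over the ranked list of the difference
#' between the weighted (exponent \code{alpha}) in-set and unweighted
#' out-of-set empirical CDFs. Scores are optionally normalized by their
#' range across samples. Signature genes absent from the matrix are dropped
#' with a warning.
#'
#' @param expr Genes x samples expression matrix (any monotone scale).
#' @param signatures Character vector (one set) or named list of sets.
#' @param alpha Rank weighting exponent (default 0.25).
#' @param normalize Divide each set's scores by their across-sample range
#'   (default TRUE; skipped for single-sample input).
#' @return Numeric vector (one set) or sets x samples matrix.
#' @export
ssgsea_score <- function(expr, signatures, alpha = 0.25, normalize = TRUE) {
  expr <- as.matrix(expr)
  single <- !is.list(signatures)
  if (single) signatures <- list(set = signatures)
  out <- t(vapply(signatures, function(sig) {
    sig <- unique(sig)
    present <- sig %in% rownames(expr)
    if (!all(present)) {
      warning(sum(!present), " signature gene(s) absent from matrix dropped")
      sig <- sig[present]
    }
    if (length(sig) < 1 || length(sig) >= nrow(expr))
      stop("signature must be a nonempty proper subset of the matrix genes")
    in_set <- rownames(expr) %in% sig
    s <- apply(expr, 2, .ssgsea_one, in_set = in_set, alpha = alpha)
    if (normalize && ncol(expr) > 1 && diff(range(s)) > 0)
      s <- s / diff(range(s))
    s
  }, numeric(ncol(expr))))
  if (single) out[1, ] else out
}

#' Myeloid-to-lymphoid skew
#'
#' Difference of per-sample myeloid and lymphoid signature scores (both on
#' the same single-sample GSEA scale); positive values indicate
#' myeloid-dominated samples.
#'
#' @param myeloid,lymphoid Numeric score vectors of equal length.
#' @return Numeric vector of skew values.
#' @export
myeloid_lymphoid_skew <- function(myeloid, lymphoid) {
  stopifnot(length(myeloid) == length(lymphoid))
  myeloid - lymphoid
}

#' Derive exclusive compartment marker signatures from pairwise DGE tables
#'
#' A gene qualifies for a compartment when it is significantly up-regulated
#' (padj <= \code{padj_cut}, log2FC > 0) in at least one of the
#' compartment's clusters against a cluster outside the compartment, and is
#' not significantly up-regulated for any other compartment. Qualifying
#' genes are ranked by their best adjusted p-value and the top \code{top_n}
#' retained per compartment.
#'
#' @param dge Data frame of pairwise cluster DGE results with columns
#'   \code{cluster}, \code{versus}, \code{gene}, \code{log2fc}, \code{padj}
#'   (each row: the gene's change in \code{cluster} relative to
#'   \code{versus}).
#' @param compartments Named character vector mapping cluster -> compartment
#'   (e.g. myeloid / lymphoid / other).
#' @param top_n Signature size per compartment (default 50).
#' @param padj_cut Significance cutoff (default 0.05).
#' @return Named list of character vectors, one per compartment present in
#'   the map (excluding clusters mapped to NA).
#' @export
derive_compartment_signatures <- function(dge, compartments, top_n = 50,
                                          padj_cut = 0.05) {
  stopifnot(all(c("cluster", "versus", "gene", "log2fc", "padj") %in%
                  names(dge)))
  dge$comp <- compartments[dge$cluster]
  dge$comp_vs <- compartments[dge$versus]
  comps <- unique(stats::na.omit(unname(compartments)))
  up <- lapply(comps, function(cc) {
    rows <- dge$comp %in% cc & !(dge$comp_vs %in% cc) &
      !is.na(dge$padj) & dge$padj <= padj_cut & dge$log2fc > 0
    d <- dge[rows, , drop = FALSE]
    if (!nrow(d)) return(data.frame(gene = character(0),
                                    padj = numeric(0)))
    best <- tapply(d$padj, d$gene, min)
    data.frame(gene = names(best), padj = as.numeric(best),
               stringsAsFactors = FALSE)
  })
  names(up) <- comps
  out <- lapply(comps, function(cc) {
    others <- unlist(lapply(setdiff(comps, cc),
                            function(o) up[[o]]$gene))
    d <- up[[cc]][!(up[[cc]]$gene %in% others), , drop = FALSE]
    d <- d[order(d$padj, d$gene), , drop = FALSE]
    if (nrow(d) < top_n)
      warning("compartment ", cc, ": only ", nrow(d),
              " exclusive genes (top_n = ", top_n, ")")
    utils::head(d$gene, top_n)
  })
  names(out) <- comps
  out
}
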