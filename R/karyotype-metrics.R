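# Per-library and per-sample karyotype metrics from binned single-cell
# copy-number calls.

#' Binned copy-number matrix container
#'
#' @param cn Integer matrix, cells in rows, genomic bins in columns.
#' @param bins Data frame with \code{chrom}, \code{start}, \code{end} and
#'   \code{size} (bp) per bin, ordered by chromosome then position.
#' @param expected Expected euploid copy number: scalar or per-bin vector
#'   (default 2; the sex-chromosome expectation and whole-genome-doubled
#'   samples are handled by supplying a different value).
#' @param reads Optional matrix of per-cell per-bin read counts (same
#'   dimensions as \code{cn}), used by \code{\link{library_qc}}.
#' @return An object of class \code{cn_matrix}.
#' @export
cn_matrix <- function(cn, bins, expected = 2, reads = NULL) {
  cn <- as.matrix(cn)
  stopifnot(is.data.frame(bins), nrow(bins) == ncol(cn),
            all(c("chrom", "size") %in% names(bins)),
            all(bins$size > 0), all(cn >= 0))
  if (!is.null(reads)) stopifnot(all(dim(reads) == dim(cn)))
  expected <- rep_len(expected, ncol(cn))
  structure(list(cn = cn, bins = bins, expected = expected, reads = reads),
            class = "cn_matrix")
}

#' Library quality control by read depth per chromosome copy
#'
#' A library (cell) is kept when its mean over bins of reads per copy
#' (reads / copy number, excluding zero-copy bins) is at least
#' \code{min_reads_per_copy}. Without read counts, QC is skipped with a
#' warning and all cells kept.
#'
#' @param x A \code{\link{cn_matrix}}.
#' @param min_reads_per_copy Threshold (default 10).
#' @return Logical vector over cells: TRUE = kept.
#' @export
library_qc <- function(x, min_reads_per_copy = 10) {
  stopifnot(inherits(x, "cn_matrix"))
  if (is.null(x$reads)) {
    warning("no read counts supplied: library QC skipped, all cells kept")
    return(rep(TRUE, nrow(x$cn)))
  }
  vapply(seq_len(nrow(x$cn)), function(i) {
    cn <- x$cn[i, ]; rd <- x$reads[i, ]
    ok <- cn > 0
    if (!any(ok)) return(FALSE)
    mean(rd[ok] / cn[ok]) >= min_reads_per_copy
  }, logical(1))
}

#' Aneuploidy scores
#'
#' Per-bin score = |observed copy number - expected euploid copy number|;
#' the library (cell) score is the bin-size-weighted average of bin scores,
#' and the sample score is the mean of library scores.
#'
#' @param x A \code{\link{cn_matrix}}.
#' @param cells Optional logical/integer subset of cells (e.g. the QC-kept
#'   set).
#' @return List with \code{per_cell} (named numeric) and \code{sample}
#'   (scalar).
#' @export
aneuploidy_score <- function(x, cells = NULL) {
  stopifnot(inherits(x, "cn_matrix"))
  cn <- if (is.null(cells)) x$cn else x$cn[cells, , drop = FALSE]
  w <- x$bins$size / sum(x$bins$size)
  dev <- abs(sweep(cn, 2, x$expected))
  per_cell <- as.numeric(dev %*% w)
  names(per_cell) <- rownames(cn)
  list(per_cell = per_cell, sample = mean(per_cell))
}

#' Between-cell karyotype heterogeneity score
#'
#' Per bin, the proportion of unordered cell pairs with differing copy
#' number; the sample score is the bin-size-weighted average of bin scores.
#' Discordance is plain inequality of integer copy-number states.
#'
#' @param x A \code{\link{cn_matrix}}.
#' @param cells Optional subset of cells.
#' @return List with \code{per_bin} (numeric in [0,1]) and \code{sample}.
#' @export
heterogeneity_score <- function(x, cells = NULL) {
  stopifnot(inherits(x, "cn_matrix"))
  cn <- if (is.null(cells)) x$cn else x$cn[cells, , drop = FALSE]
  n <- nrow(cn)
  if (n < 2) stop("heterogeneity requires at least 2 cells")
  n_pairs <- choose(n, 2)
  per_bin <- apply(cn, 2, function(v) {
    tab <- table(v)
    (n_pairs - sum(choose(tab, 2))) / n_pairs
  })
  w <- x$bins$size / sum(x$bins$size)
  list(per_bin = as.numeric(per_bin), sample = sum(per_bin * w))
}

#' Structural breakpoints per megabase
#'
#' A breakpoint is an adjacent same-chromosome bin pair whose copy numbers
#' differ within a cell. The per-cell rate is the breakpoint count divided
#' by the genome length in Mb. Single-bin chromosomes contribute no pairs.
#'
#' @param x A \code{\link{cn_matrix}}.
#' @param cells Optional subset of cells.
#' @return Named numeric vector of per-cell rates (breakpoints / Mb).
#' @export
breakpoints_per_mb <- function(x, cells = NULL) {
  stopifnot(inherits(x, "cn_matrix"))
  cn <- if (is.null(cells)) x$cn else x$cn[cells, , drop = FALSE]
  genome_mb <- sum(x$bins$size) / 1e6
  same_chrom <- x$bins$chrom[-1] == x$bins$chrom[-nrow(x$bins)]
  counts <- apply(cn, 1, function(v) {
    sum((v[-1] != v[-length(v)]) & same_chrom)
  })
  out <- counts / genome_mb
  names(out) <- rownames(cn)
  out
}

#' All karyotype scores for one sample
#'
#' Convenience wrapper: applies library QC (when read counts exist), then
#' computes aneuploidy, heterogeneity and breakpoint metrics on the kept
#' cells.
#'
#' @param x A \code{\link{cn_matrix}}.
#' @param min_reads_per_copy QC threshold passed to \code{\link{library_qc}}.
#' @return List with \code{kept}, \code{aneuploidy}, \code{heterogeneity}
#'   and \code{breakpoints_per_mb}.
#' @export
karyotype_scores <- function(x, min_reads_per_copy = 10) {
  kept <- if (is.null(x$reads)) rep(TRUE, nrow(x$cn))
          else library_qc(x, min_reads_per_copy)
  list(kept = kept,
       aneuploidy = aneuploidy_score(x, kept),
       heterogeneity = heterogeneity_score(x, kept),
       breakpoints_per_mb = breakpoints_per_mb(x, kept))
}
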