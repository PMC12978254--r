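# Plain-text readers/writers for the tables the analyses exchange.

#' Write a count matrix with metadata
#'
#' Counts go to a TSV with gene identifiers in the first column; metadata to
#' a CSV alongside.
#'
#' @param counts Genes x samples matrix.
#' @param meta Sample metadata data frame (rownames or a \code{sample}
#'   column aligned with the count columns).
#' @param prefix Output path prefix; writes \code{<prefix>_counts.tsv} and
#'   \code{<prefix>_meta.csv}.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(counts, meta, prefix) {
  cp <- paste0(prefix, "_counts.tsv")
  mp <- paste0(prefix, "_meta.csv")
  utils::write.table(data.frame(gene = rownames(counts), counts,
                                check.names = FALSE),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(meta, mp, row.names = FALSE)
  invisible(c(counts = cp, meta = mp))
}

#' Read a count matrix written by \code{\link{write_counts}}
#'
#' @param prefix Path prefix used at write time.
#' @return List with \code{counts} matrix and \code{meta} data frame.
#' @export
read_counts <- function(prefix) {
  d <- utils::read.delim(paste0(prefix, "_counts.tsv"),
                         check.names = FALSE)
  counts <- as.matrix(d[, -1, drop = FALSE])
  rownames(counts) <- d[[1]]
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"),
                          stringsAsFactors = FALSE)
  list(counts = counts, meta = meta)
}

#' Write a copy-number matrix as TSV plus a BED-like bin table
#'
#' @param x A \code{\link{cn_matrix}}.
#' @param prefix Writes \code{<prefix>_cn.tsv}, \code{<prefix>_bins.bed}
#'   and, when read counts exist, \code{<prefix>_reads.tsv}.
#' @return Invisibly, the paths.
#' @export
write_cn <- function(x, prefix) {
  stopifnot(inherits(x, "cn_matrix"))
  cp <- paste0(prefix, "_cn.tsv"); bp <- paste0(prefix, "_bins.bed")
  utils::write.table(data.frame(cell = rownames(x$cn), x$cn,
                                check.names = FALSE),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$bins[, c("chrom", "start", "end")], bp, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths <- c(cn = cp, bins = bp)
  if (!is.null(x$reads)) {
    rp <- paste0(prefix, "_reads.tsv")
    utils::write.table(data.frame(cell = rownames(x$reads), x$reads,
                                  check.names = FALSE),
                       rp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, reads = rp)
  }
  invisible(paths)
}

#' Read a copy-number matrix written by \code{\link{write_cn}}
#'
#' @param prefix Path prefix used at write time.
#' @param expected Expected euploid copy number (default 2).
#' @return A \code{\link{cn_matrix}}.
#' @export
read_cn <- function(prefix, expected = 2) {
  d <- utils::read.delim(paste0(prefix, "_cn.tsv"), check.names = FALSE)
  cn <- as.matrix(d[, -1, drop = FALSE]); rownames(cn) <- d[[1]]
  bed <- utils::read.delim(paste0(prefix, "_bins.bed"), header = FALSE,
                           col.names = c("chrom", "start", "end"))
  bed$size <- bed$end - bed$start + 1
  reads <- NULL
  rp <- paste0(prefix, "_reads.tsv")
  if (file.exists(rp)) {
    r <- utils::read.delim(rp, check.names = FALSE)
    reads <- as.matrix(r[, -1, drop = FALSE]); rownames(reads) <- r[[1]]
  }
  cn_matrix(cn, bed, expected = expected, reads = reads)
}

#' Serialize simulation ground truth to JSON
#'
#' @param truth Truth list from a generator.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
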