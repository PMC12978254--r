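#' Median-of-ratios size factors
#'
#' Sample-level normalization factors computed from the geometric-mean
#' reference, as used for bulk RNA-seq count normalization. Wraps the
#' DESeq2 implementation.
#'
#' @param counts Nonnegative integer matrix, genes in rows, samples in columns.
#' @return Numeric vector of size factors, one per column.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), all(counts >= 0))
  DESeq2::estimateSizeFactorsForMatrix(counts)
}

#' Normalize counts by size factors and log-transform
#'
#' Divides each column by its median-of-ratios size factor and applies
#' log2(x + 1). This is the variance-stabilizing stand-in used throughout:
#' it matches the log scale on which synthetic effect sizes are defined.
#'
#' @param counts Count matrix (genes x samples).
#' @return Matrix of log2 normalized values, same dimensions.
#' @export
normalize_log2 <- function(counts) {
  counts <- as.matrix(counts)
  sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional description field (second GMT column).
#' @return Invisibly, the path.
#' @export
write_gmt <- function(gene_sets, path, description = "") {
  stopifnot(is.list(gene_sets), length(names(gene_sets)) == length(gene_sets))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Internal: check a single positive finite scalar
.check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %s", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %s", name, lower), call. = FALSE)
  invisible(x)
}
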