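# In-situ micronucleus scoring from segmented-object tables.

#' Filter candidate cGAS+ micronucleus detections
#'
#' Retains foci whose area lies within the detection window (inclusive
#' bounds) and whose mean cGAS intensity reaches the per-tumor threshold.
#' The intensity threshold is an explicit input because it is tuned per
#' tumor; \code{\link{otsu_threshold}} offers a heuristic default.
#'
#' @param foci Data frame with at least \code{area} and
#'   \code{cgas_intensity} columns.
#' @param area_min,area_max Area window in um^2 (defaults 0.25 and 7.5).
#' @param intensity_threshold Minimum mean cGAS intensity.
#' @return The filtered foci table. Records with negative area are dropped
#'   with a warning.
#' @export
filter_mn_candidates <- function(foci, area_min = 0.25, area_max = 7.5,
                                 intensity_threshold = 0) {
  stopifnot(is.data.frame(foci), all(c("area", "cgas_intensity") %in%
                                       names(foci)))
  bad <- !is.na(foci$area) & foci$area < 0
  if (any(bad)) {
    warning(sum(bad), " focus record(s) with negative area rejected")
    foci <- foci[!bad, , drop = FALSE]
  }
  keep <- foci$area >= area_min & foci$area <= area_max &
    foci$cgas_intensity >= intensity_threshold
  foci[which(keep), , drop = FALSE]
}

#' Otsu's threshold on focus intensities
#'
#' Heuristic helper for picking a per-tumor cGAS intensity threshold by
#' maximizing between-class variance of the intensity histogram. The
#' reference workflow tunes this threshold per tumor by inspection; this
#' helper is an automated stand-in, flagged as such.
#'
#' @param intensity Numeric vector of focus intensities.
#' @param n_breaks Number of histogram bins.
#' @return A scalar threshold.
#' @export
otsu_threshold <- function(intensity, n_breaks = 256) {
  x <- intensity[is.finite(intensity)]
  if (length(x) < 2 || diff(range(x)) == 0) return(min(x, Inf))
  h <- graphics::hist(x, breaks = n_breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids) / pmax(w1, .Machine$double.eps)
  mu_t <- sum(p * mids)
  mu2 <- (mu_t - cumsum(p * mids)) / pmax(1 - w1, .Machine$double.eps)
  between <- w1 * (1 - w1) * (mu1 - mu2)^2
  mids[which.max(between[-length(between)])]
}

#' Compute the cGAS+ MN score of a tumor
#'
#' Counts tumor-compartment foci and normalizes to the number of tumor cells:
#' score = 100 * n_mn / n_tumor_cells (MN per 100 tumor cells). Artifact
#' cells never enter the denominator; stromal foci never enter the numerator.
#'
#' @param foci Filtered foci table with a \code{compartment} column.
#' @param cells Segmented-cell table with a \code{compartment} column
#'   containing values in \{tumor, stroma, artifact\}.
#' @param tumor_id Optional identifier carried into the result.
#' @return Data frame with \code{tumor_id}, \code{n_mn},
#'   \code{n_tumor_cells}, \code{score} and a \code{flagged} logical (TRUE
#'   when there are no tumor cells and the score is undefined).
#' @export
compute_mn_score <- function(foci, cells, tumor_id = NA_character_) {
  stopifnot(is.data.frame(cells), "compartment" %in% names(cells))
  n_tumor <- sum(cells$compartment == "tumor")
  n_mn <- if (nrow(foci)) sum(foci$compartment == "tumor") else 0L
  flagged <- n_tumor == 0
  if (flagged) warning("no tumor cells: MN score undefined")
  data.frame(tumor_id = tumor_id, n_mn = n_mn, n_tumor_cells = n_tumor,
             score = if (flagged) NA_real_ else 100 * n_mn / n_tumor,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Autofluorescence-normalized marker intensities
#'
#' Divides each cell's mean marker intensity by its mean inferred
#' autofluorescence, then averages the per-cell normalized values within
#' each compartment class. Cells with non-positive autofluorescence are
#' excluded with a warning; artifact cells are excluded from compartment
#' summaries.
#'
#' @param cells Segmented-cell table with \code{autofluorescence},
#'   \code{compartment} and one or more marker intensity columns.
#' @param markers Character vector of marker column names (default: all
#'   columns ending in \code{"_intensity"}).
#' @return List with \code{per_cell} (the input plus
#'   \code{<marker>_norm} columns) and \code{per_compartment} (long data
#'   frame: compartment, marker, mean normalized value, n cells).
#' @export
normalize_marker_intensities <- function(cells, markers = NULL) {
  stopifnot(is.data.frame(cells), "autofluorescence" %in% names(cells))
  if (is.null(markers))
    markers <- grep("_intensity$", names(cells), value = TRUE)
  if (!length(markers)) stop("no marker intensity columns found")
  bad <- !is.finite(cells$autofluorescence) | cells$autofluorescence <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with non-positive autofluorescence excluded")
    cells <- cells[!bad, , drop = FALSE]
  }
  for (m in markers)
    cells[[paste0(m, "_norm")]] <- cells[[m]] / cells$autofluorescence
  keep <- cells$compartment %in% c("tumor", "stroma")
  per_comp <- do.call(rbind, lapply(markers, function(m) {
    v <- tapply(cells[[paste0(m, "_norm")]][keep],
                cells$compartment[keep], mean)
    data.frame(compartment = names(v), marker = m,
               mean_normalized = as.numeric(v),
               n_cells = as.integer(table(cells$compartment[keep])[names(v)]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_comp) <- NULL
  list(per_cell = cells, per_compartment = per_comp)
}
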