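# Kernel-density CIN hotspot mapping and cell-type fold enrichment.

#' Apply an affine transform to 2-D points
#'
#' Used to project micronucleus detections from one stained section onto an
#' adjacent section given a known registration transform (registration
#' estimation itself is out of scope).
#'
#' @param points Data frame or matrix with columns \code{x}, \code{y} (or two
#'   unnamed columns).
#' @param affine 2x3 matrix \code{[A | b]}: new = A \%*\% (x, y) + b.
#' @return Object of the same shape with transformed coordinates.
#' @export
project_points <- function(points, affine) {
  stopifnot(is.matrix(affine), nrow(affine) == 2, ncol(affine) == 3)
  df <- is.data.frame(points)
  xy <- if (df) cbind(points$x, points$y) else as.matrix(points)[, 1:2]
  new <- t(affine[, 1:2] %*% t(xy) + affine[, 3])
  if (df) {
    points$x <- new[, 1]; points$y <- new[, 2]; points
  } else new
}

# Ray-casting point-in-polygon (polygon as matrix of vertices, closed or not)
.in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite(cross))
    j <- i
  }
  inside
}

#' Kernel density estimate of micronucleus positions
#'
#' Product-Gaussian KDE on a regular grid via \code{MASS::kde2d}. The default
#' bandwidth is the quartile-robust normal-reference rule per axis
#' (\code{MASS::bandwidth.nrd}), expressed here as the kernel standard
#' deviation and floored at 2 um so that coincident points still yield a
#' finite density. An optional tissue mask is taken as the convex hull of
#' supplied cell centroids, dilated by one grid cell.
#'
#' @param mn_points Data frame with \code{x}, \code{y} of micronucleus
#'   detections (at least 11 points expected; tumors with <= 10 detections
#'   should be excluded upstream).
#' @param field_bounds Numeric length-4: xmin, xmax, ymin, ymax.
#' @param grid_n Grid nodes per axis (default 100).
#' @param bandwidth Kernel sd per axis (length 1 or 2); NULL for the
#'   normal-reference default.
#' @param mask_points Optional data frame of cell centroids defining the
#'   tissue mask; NULL masks nothing.
#' @return A \code{density_grid}: list with grid axes \code{x}, \code{y},
#'   density matrix \code{z} (integrating to ~1 over the field), logical
#'   \code{mask}, and \code{percentile} (NA until
#'   \code{\link{quantize_density}}).
#' @export
estimate_kde <- function(mn_points, field_bounds, grid_n = 100,
                         bandwidth = NULL, mask_points = NULL) {
  stopifnot(nrow(mn_points) >= 1, length(field_bounds) == 4)
  if (is.null(bandwidth)) {
    bw <- c(MASS::bandwidth.nrd(mn_points$x),
            MASS::bandwidth.nrd(mn_points$y)) / 4
  } else bw <- rep_len(bandwidth, 2)
  if (any(bw < 2)) {
    if (!is.null(bandwidth) || any(bw <= 0))
      warning("bandwidth below 2 um floor; floor applied")
    bw <- pmax(bw, 2)
  }
  k <- MASS::kde2d(mn_points$x, mn_points$y, h = 4 * bw, n = grid_n,
                   lims = field_bounds)
  mask <- matrix(TRUE, grid_n, grid_n)
  if (!is.null(mask_points) && nrow(mask_points) >= 3) {
    hull <- as.matrix(mask_points[grDevices::chull(mask_points$x,
                                                   mask_points$y),
                                  c("x", "y")])
    gg <- expand.grid(x = k$x, y = k$y)
    inh <- matrix(.in_polygon(gg$x, gg$y, hull), grid_n, grid_n)
    # dilate by one grid cell (3x3 neighborhood)
    pad <- matrix(FALSE, grid_n + 2, grid_n + 2)
    pad[2:(grid_n + 1), 2:(grid_n + 1)] <- inh
    dil <- matrix(FALSE, grid_n, grid_n)
    for (di in 0:2) for (dj in 0:2)
      dil <- dil | pad[di + seq_len(grid_n), dj + seq_len(grid_n)]
    mask <- dil
  }
  structure(list(x = k$x, y = k$y, z = k$z, mask = mask,
                 percentile = matrix(NA_integer_, grid_n, grid_n)),
            class = "density_grid")
}

#' Quantize a density grid into integer percentile bins
#'
#' Each masked node is assigned its empirical percentile rank among masked
#' nodes, quantized into 1% bins from (0, 100]:
#' \code{ceiling(100 * rank / n)} with maximum-tie ranks, so a constant
#' density collapses to the single bin 100 and a strictly increasing density
#' over 100 nodes yields bins 1..100. Unmasked nodes keep NA.
#'
#' @param grid A \code{density_grid} from \code{\link{estimate_kde}}.
#' @return The grid with its \code{percentile} matrix filled in.
#' @export
quantize_density <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  v <- grid$z[grid$mask]
  r <- rank(v, ties.method = "max")
  perc <- as.integer(ceiling(100 * r / length(v)))
  out <- matrix(NA_integer_, nrow(grid$z), ncol(grid$z))
  out[grid$mask] <- perc
  grid$percentile <- out
  grid
}

# Nearest-node percentile for each point (regular grid)
.node_percentile <- function(x, y, grid) {
  ix <- pmin(pmax(round(stats::approx(grid$x, seq_along(grid$x),
                                      xout = x, rule = 2)$y), 1),
             length(grid$x))
  iy <- pmin(pmax(round(stats::approx(grid$y, seq_along(grid$y),
                                      xout = y, rule = 2)$y), 1),
             length(grid$y))
  grid$percentile[cbind(ix, iy)]
}

#' Cell-type fold enrichment inside hotspots at one density threshold
#'
#' Hotspot = grid nodes whose quantized density percentile is at or above
#' the threshold. Every non-artifact cell is mapped to its nearest grid
#' node; for cell type t the fold enrichment is the type's share of all
#' cells inside the hotspot divided by its share outside:
#' FE = [n(t, in) / n(all, in)] / [n(t, out) / n(all, out)].
#' A type is excluded at this threshold when it has no cells inside or no
#' cells outside.
#'
#' @param cells Segmented-cell table (\code{x}, \code{y}, \code{cell_type},
#'   \code{compartment}).
#' @param grid A quantized \code{density_grid}.
#' @param threshold Percentile threshold (e.g. 25--95).
#' @param tumor_id Identifier carried into the records.
#' @return Data frame of enrichment records (possibly zero rows when the
#'   hotspot or remainder region is empty).
#' @export
enrichment_at_threshold <- function(cells, grid, threshold,
                                    tumor_id = NA_character_) {
  stopifnot(inherits(grid, "density_grid"))
  if (all(is.na(grid$percentile)))
    stop("grid has no percentiles; call quantize_density() first")
  cells <- cells[cells$compartment != "artifact" & !is.na(cells$cell_type), ,
                 drop = FALSE]
  perc <- .node_percentile(cells$x, cells$y, grid)
  ok <- !is.na(perc)
  cells <- cells[ok, , drop = FALSE]; perc <- perc[ok]
  inside <- perc >= threshold
  n_in <- sum(inside); n_out <- sum(!inside)
  empty <- data.frame(tumor_id = character(0), cell_type = character(0),
                      threshold = integer(0), n_inside = integer(0),
                      n_outside = integer(0), total_inside = integer(0),
                      total_outside = integer(0),
                      fold_enrichment = numeric(0), stringsAsFactors = FALSE)
  if (n_in == 0 || n_out == 0) return(empty)
  recs <- lapply(unique(cells$cell_type), function(tt) {
    ti <- sum(inside & cells$cell_type == tt)
    to <- sum(!inside & cells$cell_type == tt)
    if (ti == 0 || to == 0) return(NULL)
    data.frame(tumor_id = tumor_id, cell_type = tt,
               threshold = as.integer(threshold),
               n_inside = ti, n_outside = to,
               total_inside = n_in, total_outside = n_out,
               fold_enrichment = (ti / n_in) / (to / n_out),
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(empty)
  do.call(rbind, recs)
}

#' Fold-enrichment sweep over density thresholds across tumors
#'
#' For each tumor (a list with quantized \code{grid} and \code{cells}) and
#' each threshold, computes per-type fold enrichment, then summarizes each
#' (cell type, threshold) across tumors: mean and median FE, a normal-theory
#' 95% CI on the median (1.58 * IQR / sqrt(n) band), and a two-sided
#' one-sample t-test of FE against 1. The test is reported as NA when fewer
#' than two tumors contribute.
#'
#' @param tumors List of lists with elements \code{cells} and \code{grid};
#'   optionally \code{tumor_id}.
#' @param thresholds Integer percentiles (default 25:95).
#' @return List with \code{records} (all per-tumor records) and
#'   \code{summary} (per type x threshold).
#' @export
threshold_sweep <- function(tumors, thresholds = 25:95) {
  records <- do.call(rbind, lapply(seq_along(tumors), function(i) {
    tu <- tumors[[i]]
    id <- if (!is.null(tu$tumor_id)) tu$tumor_id else sprintf("tumor%02d", i)
    do.call(rbind, lapply(thresholds, function(th)
      enrichment_at_threshold(tu$cells, tu$grid, th, tumor_id = id)))
  }))
  if (is.null(records) || nrow(records) == 0)
    return(list(records = records, summary = NULL))
  key <- interaction(records$cell_type, records$threshold, drop = TRUE)
  summ <- do.call(rbind, lapply(split(records, key), function(d) {
    fe <- d$fold_enrichment
    n <- length(fe)
    tt <- if (n >= 2 && stats::sd(fe) > 0) stats::t.test(fe, mu = 1)
          else NULL
    med <- stats::median(fe)
    half <- if (n >= 2) 1.58 * stats::IQR(fe) / sqrt(n) else NA_real_
    data.frame(cell_type = d$cell_type[1], threshold = d$threshold[1],
               n_tumors = n, mean_fe = mean(fe), median_fe = med,
               median_ci_lo = med - half, median_ci_hi = med + half,
               t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ[order(summ$cell_type,
                                               summ$threshold), ])
}
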