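#' Ripley K, L and H functions of a point pattern
#'
#' Second-order clustering statistics:
#' `K(r) = |A| / (n (n - 1)) * sum_{i != j} 1(d_ij <= r)`, `L = sqrt(K / pi)`
#' and `H = L - r`. `H > 0` indicates clustering, and the radius of the H
#' peak scales with cluster size. Edge correction is `"none"` (the default
#' inside cropped analysis regions, where the bias is shared across
#' compared conditions) or `"toroidal"` (wrapped distances; exact for
#' generators built on a torus).
#'
#' @param pattern A [point_pattern()].
#' @param radii_nm Radius grid in nm (default 10-500 nm in 10-nm steps).
#' @param edge_correction `"none"` or `"toroidal"`.
#' @returns A `ripley_curve`: data.frame with `r_nm`, `K`, `L`, `H`, plus
#'   attribute `peak_radius_nm`.
#' @export
ripley_k <- function(pattern, radii_nm = seq(10, 500, by = 10),
                     edge_correction = c("none", "toroidal")) {
  edge_correction <- match.arg(edge_correction)
  n <- npoints(pattern)
  if (n < 2) stop("Ripley K undefined for fewer than 2 points")
  if (max(radii_nm) > min(pattern$width_nm, pattern$height_nm) / 2)
    stop("max radius exceeds half the shorter region side")
  area <- pattern$width_nm * pattern$height_nm
  counts <- cpp_pair_counts(pattern$x, pattern$y, pattern$width_nm,
                            pattern$height_nm, radii_nm,
                            edge_correction == "toroidal")
  k <- area / (n * (n - 1)) * counts
  l <- sqrt(k / pi)
  h <- l - radii_nm
  curve <- data.frame(r_nm = radii_nm, K = k, L = l, H = h)
  class(curve) <- c("ripley_curve", "data.frame")
  attr(curve, "peak_radius_nm") <- h_peak(curve)
  curve
}

#' Radius of the Ripley H peak
#'
#' The argmax of H over the radius grid, resolved to the grid step; ties
#' take the smallest radius. When H is nowhere positive the pattern shows
#' no clustering and `NA` is returned.
#'
#' @param curve A `ripley_curve`.
#' @returns Peak radius in nm, or `NA_real_` when H <= 0 everywhere.
#' @export
h_peak <- function(curve) {
  if (all(curve$H <= 0)) return(NA_real_)
  curve$r_nm[which.max(curve$H)]
}

#' Getis-Franklin local cluster map
#'
#' Per-point local statistic
#' `L_i(r) = sqrt(|A| * sum_{j != i} 1(d_ij <= r) / (pi (n - 1)))`
#' interpolated onto a regular grid (inverse-distance weighting over points
#' within `r_local_nm`; grid cells farther than `r_local_nm` from every
#' point are 0).
#'
#' @param pattern A [point_pattern()].
#' @param r_local_nm Local analysis radius in nm (default 50).
#' @param grid_step_nm Grid pitch in nm (default 5).
#' @returns A `cluster_map`: list with `L_i` (per point), `map` (matrix,
#'   rows = y), `grid_step_nm`, `r_local_nm`, `pattern`; `binary` and
#'   `labels` are filled by [segment_clusters()].
#' @export
getis_franklin_map <- function(pattern, r_local_nm = 50, grid_step_nm = 5) {
  n <- npoints(pattern)
  area <- pattern$width_nm * pattern$height_nm
  li <- if (n >= 2) {
    cnt <- cpp_local_counts(pattern$x, pattern$y, pattern$width_nm,
                            pattern$height_nm, r_local_nm, FALSE)
    sqrt(area * cnt / (pi * (n - 1)))
  } else numeric(n)
  map <- cpp_idw_map(pattern$x, pattern$y, li, pattern$width_nm,
                     pattern$height_nm, grid_step_nm, r_local_nm)
  structure(list(L_i = li, map = map, grid_step_nm = grid_step_nm,
                 r_local_nm = r_local_nm, pattern = pattern,
                 binary = NULL, labels = NULL, threshold = NULL),
            class = "cluster_map")
}

#' Threshold and label a Getis-Franklin map into clusters
#'
#' Default threshold policy: the `quantile` (99th percentile) of the
#' per-point `L_i(r_local)` values pooled over `n_sim` CSR simulations
#' matched to the pattern's point count and region. Grid cells at or above
#' the threshold are foreground; 8-connected components with at least
#' `min_cells` grid cells become clusters.
#'
#' @param map A `cluster_map`.
#' @param threshold Numeric threshold overriding the CSR calibration.
#' @param n_sim CSR simulations for the null calibration (default 100).
#' @param quantile_prob Null quantile (default 0.99).
#' @param min_cells Minimum component size in grid cells (default 3).
#' @param seed RNG seed for the calibration simulations.
#' @returns The `cluster_map` with `binary`, `labels` and `threshold` set.
#' @export
segment_clusters <- function(map, threshold = NULL, n_sim = 100,
                             quantile_prob = 0.99, min_cells = 3,
                             seed = 1) {
  p <- map$pattern
  n <- npoints(p)
  if (is.null(threshold)) {
    if (n < 2) {
      threshold <- Inf
    } else {
      set.seed(seed)
      area <- p$width_nm * p$height_nm
      null_li <- unlist(lapply(seq_len(n_sim), function(s) {
        x <- runif(n, 0, p$width_nm); y <- runif(n, 0, p$height_nm)
        cnt <- cpp_local_counts(x, y, p$width_nm, p$height_nm,
                                map$r_local_nm, FALSE)
        sqrt(area * cnt / (pi * (n - 1)))
      }))
      threshold <- quantile(null_li, quantile_prob, names = FALSE)
    }
  }
  binary <- map$map >= threshold
  labels <- cpp_label8(binary)
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0])
    small <- which(sizes < min_cells)
    if (length(small)) {
      binary[labels %in% small] <- FALSE
      labels <- cpp_label8(binary)
    }
  }
  map$binary <- binary
  map$labels <- labels
  map$threshold <- threshold
  map
}

#' Per-region cluster metrics from a segmented map
#'
#' The summary panel reported per analysis region: overall localization
#' density, mean cluster area, density of events inside clusters, number of
#' clusters, and the fraction of events inside clusters.
#'
#' @param map A segmented `cluster_map`.
#' @returns A `cluster_metrics` list: `density_per_um2`,
#'   `mean_cluster_area_nm2`, `in_cluster_density_per_um2`, `n_clusters`,
#'   `fraction_in_clusters`.
#' @export
cluster_metrics <- function(map) {
  if (is.null(map$binary)) stop("segment_clusters must be run first")
  p <- map$pattern
  n <- npoints(p)
  step <- map$grid_step_nm
  n_clusters <- max(map$labels)
  cell_area <- step^2
  # which grid cell holds each point (map rows = y)
  in_fg <- if (n) {
    gx <- pmin(ncol(map$map), pmax(1, floor(p$x / step) + 1))
    gy <- pmin(nrow(map$map), pmax(1, floor(p$y / step) + 1))
    map$binary[cbind(gy, gx)]
  } else logical(0)
  fg_cells <- sum(map$binary)
  structure(list(
    density_per_um2 = pattern_density(p),
    mean_cluster_area_nm2 = if (n_clusters > 0)
      mean(tabulate(map$labels[map$labels > 0]) * cell_area) else NA_real_,
    in_cluster_density_per_um2 = if (fg_cells > 0)
      sum(in_fg) / (fg_cells * cell_area / 1e6) else NA_real_,
    n_clusters = n_clusters,
    fraction_in_clusters = if (n) sum(in_fg) / n else 0
  ), class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "cluster_metrics: %.1f /um^2 overall, %d clusters, mean area %.0f nm^2,",
    "\n  in-cluster density %.0f /um^2, fraction in clusters %.3f\n"),
    x$density_per_um2, x$n_clusters,
    ifelse(is.na(x$mean_cluster_area_nm2), 0, x$mean_cluster_area_nm2),
    ifelse(is.na(x$in_cluster_density_per_um2), 0,
           x$in_cluster_density_per_um2),
    x$fraction_in_clusters))
  invisible(x)
}
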