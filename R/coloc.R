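#' Coordinate-based colocalization (CBC) of two channels
#'
#' For each localization `a` of channel A and radius grid
#' `r_k = k r_max / n_steps`, the normalized neighbour-density profiles
#' `D_AA(r_k) = N_A(a, r_k) / N_A(a, r_max) * r_max^2 / r_k^2` (A-neighbours,
#' excluding `a` itself) and `D_AB` (B-neighbours, excluding zero-distance
#' partners) are rank-correlated (Spearman) and the correlation is damped by
#' the nearest-B distance: `C_a = S_a * exp(-d(a, nearest B) / r_max)`.
#' Scores lie in \[-1, 1\]; a profile without variance gives score 0.
#' Scores above 0.8 are conventionally counted as strongly colocalized and
#' their fraction is the per-cell summary.
#'
#' @param A,B [point_pattern()]s sharing a region.
#' @param r_max_nm Largest evaluation radius in nm (default 500).
#' @param n_steps Number of radius steps (default 20).
#' @param threshold Score cut-off for `fraction_above` (default 0.8).
#' @returns A `cbc_result`: list with `scores` (per A-localization),
#'   `fraction_above`, `threshold`, `mean_score`.
#' @export
cbc <- function(A, B, r_max_nm = 500, n_steps = 20, threshold = 0.8) {
  if (npoints(A) < 10 || npoints(B) < 10)
    stop("CBC needs at least 10 localizations per channel")
  radii <- seq_len(n_steps) * r_max_nm / n_steps
  caa <- cpp_cross_counts(A$x, A$y, A$x, A$y, A$width_nm, A$height_nm,
                          radii, TRUE)
  cab <- cpp_cross_counts(A$x, A$y, B$x, B$y, A$width_nm, A$height_nm,
                          radii, TRUE)
  nnd_b <- cpp_nn(A$x, A$y, B$x, B$y, A$width_nm, A$height_nm)$dist
  scale <- r_max_nm^2 / radii^2
  scores <- vapply(seq_len(npoints(A)), function(i) {
    if (caa[i, n_steps] == 0 || cab[i, n_steps] == 0) return(0)
    daa <- caa[i, ] / caa[i, n_steps] * scale
    dab <- cab[i, ] / cab[i, n_steps] * scale
    if (sd(daa) == 0 || sd(dab) == 0) return(0)
    suppressWarnings(cor(daa, dab, method = "spearman")) *
      exp(-nnd_b[i] / r_max_nm)
  }, numeric(1))
  structure(list(scores = scores,
                 fraction_above = mean(scores > threshold),
                 threshold = threshold,
                 mean_score = mean(scores)),
            class = "cbc_result")
}

#' Nearest-neighbour distances from channel A to channel B
#'
#' Exact cross-channel nearest-neighbour distances (spatial-index
#' accelerated, identical to brute force), histogrammed in 10-nm bins; the
#' modal bin centre is the summary the method reports as the NND "peak".
#'
#' @param A,B [point_pattern()]s.
#' @param bin_nm Histogram bin width in nm (default 10).
#' @returns An `nnd_result`: list with `distances`, `breaks_nm`, `counts`,
#'   `mode_nm` (modal bin centre).
#' @export
nnd <- function(A, B, bin_nm = 10) {
  if (npoints(B) < 1) stop("channel B is empty")
  d <- cpp_nn(A$x, A$y, B$x, B$y, A$width_nm, A$height_nm)$dist
  breaks <- seq(0, (max(d) %/% bin_nm + 1) * bin_nm, by = bin_nm)
  counts <- tabulate(pmin(length(breaks) - 1, d %/% bin_nm + 1),
                     length(breaks) - 1)
  mode_nm <- breaks[which.max(counts)] + bin_nm / 2
  structure(list(distances = d, breaks_nm = breaks, counts = counts,
                 mode_nm = mode_nm),
            class = "nnd_result")
}

#' Reversed-coordinate negative control
#'
#' Generates a randomized control channel with the same number of events
#' and the same intra-channel structure, but destroyed cross-channel
#' registration. Default mode reflects every coordinate through the region
#' centre (`x -> width - x`, `y -> height - y`; an involution); mode
#' `"shuffle-pairing"` re-pairs the x list with the reversed y list.
#'
#' @param P A [point_pattern()].
#' @param mode `"reflect"` (default) or `"shuffle-pairing"`.
#' @returns A [point_pattern()] with the same number of points.
#' @export
randomize_control <- function(P, mode = c("reflect", "shuffle-pairing")) {
  mode <- match.arg(mode)
  if (mode == "reflect")
    point_pattern(P$width_nm - P$x, P$height_nm - P$y,
                  P$width_nm, P$height_nm)
  else
    point_pattern(P$x, rev(P$y), P$width_nm, P$height_nm)
}

#' Per-point Voronoi densities of a pattern
#'
#' First-rank Voronoi densities: the tessellation is clipped to the region
#' and each point's density is the inverse of its cell area. Exactly
#' collinear degenerate inputs are jittered by 0.01 nm with a warning.
#'
#' @param P A [point_pattern()] with at least 4 points.
#' @returns Numeric vector of densities in localizations per square
#'   micrometre, with attribute `areas_nm2`.
#' @export
voronoi_densities <- function(P) {
  n <- npoints(P)
  if (n < 4) stop("tessellation needs at least 4 points")
  x <- P$x; y <- P$y
  if (n >= 2) {
    colinear <- abs(sd(x)) < 1e-9 || abs(sd(y)) < 1e-9 ||
      any(duplicated(cbind(x, y)))
    if (colinear) {
      warning("degenerate point configuration; jittering by 0.01 nm")
      set.seed(0)
      x <- x + runif(n, -0.01, 0.01)
      y <- y + runif(n, -0.01, 0.01)
    }
  }
  areas <- cpp_voronoi_areas(x, y, P$width_nm, P$height_nm)
  dens <- 1e6 / areas
  attr(dens, "areas_nm2") <- areas
  dens
}

#' Tessellation-based colocalization of two channels
#'
#' Every localization of A union B is assigned the Voronoi-cell density of
#' each channel's tessellation at its position (`delta_A`, `delta_B`); the
#' Spearman rank correlation of the two density vectors measures
#' co-organization. For Mander's-style overlap, each channel's object mask
#' is the union of its Voronoi cells with density at least `seg_factor`
#' times the channel mean density; `M_A` is the fraction of A localizations
#' inside B's mask, and symmetrically for `M_B`.
#'
#' @param A,B [point_pattern()]s with at least 4 points each.
#' @param seg_factor Density multiple defining channel masks (default 2).
#' @returns A `tessellation_result`: list with `spearman`, `M_A`, `M_B`,
#'   `delta_A`, `delta_B`.
#' @export
tessellation_correlation <- function(A, B, seg_factor = 2) {
  dens_a <- voronoi_densities(A)
  dens_b <- voronoi_densities(B)
  # density of the containing cell = density at the nearest seed
  qx <- c(A$x, B$x); qy <- c(A$y, B$y)
  ia <- cpp_nn(qx, qy, A$x, A$y, A$width_nm, A$height_nm)$index
  ib <- cpp_nn(qx, qy, B$x, B$y, A$width_nm, A$height_nm)$index
  delta_a <- dens_a[ia]
  delta_b <- dens_b[ib]
  rho <- suppressWarnings(cor(delta_a, delta_b, method = "spearman"))
  mask_a <- dens_a >= seg_factor * mean(dens_a)
  mask_b <- dens_b >= seg_factor * mean(dens_b)
  na <- npoints(A)
  # A points: first na query points; inside B's mask when their containing
  # B cell is masked
  m_a <- if (any(mask_b)) mean(mask_b[ib[seq_len(na)]]) else {
    warning("empty B mask; Mander's M_A = 0"); 0
  }
  m_b <- if (any(mask_a)) mean(mask_a[ia[na + seq_len(npoints(B))]]) else {
    warning("empty A mask; Mander's M_B = 0"); 0
  }
  structure(list(spearman = rho, M_A = m_a, M_B = m_b,
                 delta_A = delta_a, delta_B = delta_b),
            class = "tessellation_result")
}

#' Pearson correlation of two pixel images over a mask
#'
#' @param imageA,imageB [pixel_image()]s (or matrices) of equal shape.
#' @param mask Optional logical matrix; defaults to all pixels.
#' @returns Pearson correlation coefficient.
#' @export
pearson_pixel <- function(imageA, imageB, mask = NULL) {
  va <- if (inherits(imageA, "pixel_image")) imageA$values else imageA
  vb <- if (inherits(imageB, "pixel_image")) imageB$values else imageB
  if (!identical(dim(va), dim(vb))) stop("image shapes differ")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(va), ncol(va))
  a <- va[mask]; b <- vb[mask]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0)
    stop("undefined statistic: fewer than 2 masked pixels with variance")
  cor(a, b)
}
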