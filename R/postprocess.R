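#' Quality-filter a localization table
#'
#' Keeps events with intensity strictly above `min_photons`, PSF sigma
#' inside the closed range `sigma_range_nm`, and uncertainty strictly below
#' `max_uncertainty_nm` — the published retention criteria
#' (photons > 600, sigma in \[50, 200\] nm, uncertainty < 30 nm).
#' Row order is preserved.
#'
#' @param table A `localization_table`.
#' @param min_photons Strict lower intensity bound (default 600).
#' @param sigma_range_nm Closed sigma range in nm (default `c(50, 200)`).
#' @param max_uncertainty_nm Strict upper uncertainty bound (default 30).
#' @param verbose Log removed counts per criterion.
#' @returns The filtered `localization_table`.
#' @export
filter_localizations <- function(table, min_photons = 600,
                                 sigma_range_nm = c(50, 200),
                                 max_uncertainty_nm = 30, verbose = FALSE) {
  stopifnot(min_photons >= 0, sigma_range_nm[1] <= sigma_range_nm[2],
            max_uncertainty_nm > 0)
  ok_ph <- table$photons > min_photons
  ok_sg <- table$sigma_nm >= sigma_range_nm[1] &
           table$sigma_nm <= sigma_range_nm[2]
  ok_un <- table$uncertainty_nm < max_uncertainty_nm
  if (verbose)
    message(sprintf(
      "filter: removed %d (photons), %d (sigma), %d (uncertainty) of %d",
      sum(!ok_ph), sum(!ok_sg), sum(!ok_un), nrow(table)))
  out <- table[ok_ph & ok_sg & ok_un, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# render localizations as a 2-D count histogram with given bin size (nm)
render_histogram <- function(x, y, width_nm, height_nm, bin_nm) {
  nx <- max(1L, ceiling(width_nm / bin_nm))
  ny <- max(1L, ceiling(height_nm / bin_nm))
  ix <- pmin(nx - 1L, pmax(0L, floor(x / bin_nm)))
  iy <- pmin(ny - 1L, pmax(0L, floor(y / bin_nm)))
  m <- matrix(0, ny, nx)
  m[] <- tabulate(iy + 1L + ix * ny, nx * ny)
  m
}

# circular cross-correlation shift (b relative to a) via FFT, with 3x3
# parabolic sub-bin interpolation. Returns c(dx, dy) in bins.
xcorr_shift <- function(a, b) {
  fa <- fft(a); fb <- fft(b)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(cc); nc <- ncol(cc)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  para <- function(m0, m1, m2) {
    den <- m0 - 2 * m1 + m2
    if (abs(den) < 1e-12) 0 else 0.5 * (m0 - m2) / den
  }
  dyf <- para(cc[wrap(pk[1] - 1, nr), pk[2]], cc[pk[1], pk[2]],
              cc[wrap(pk[1] + 1, nr), pk[2]])
  dxf <- para(cc[pk[1], wrap(pk[2] - 1, nc)], cc[pk[1], pk[2]],
              cc[pk[1], wrap(pk[2] + 1, nc)])
  # index p corresponds to displacement p-1, wrapped to +-n/2
  unwrap <- function(p, n) { d <- p - 1; if (d > n / 2) d - n else d }
  c(dx = unwrap(pk[2], nc) + dxf, dy = unwrap(pk[1], nr) + dyf)
}

#' Estimate sample drift by redundant image cross-correlation
#'
#' Frames are split into `n_bins` equal temporal bins; each bin is rendered
#' as a 2-D histogram with bin size `pixel_size_nm / magnification`; the
#' cross-correlation peak of bin k against bin 1 (sub-bin 3x3 parabolic
#' interpolation) gives the bin offsets; per-frame drift is linear
#' interpolation between bin midpoints with constant extrapolation at the
#' ends. Because drift accumulated within a bin smears its rendering, the
#' estimate is refined iteratively: the current track (extended linearly at
#' the ends during refinement only) is subtracted, the sharpened bins are
#' re-correlated, and the residual offsets are accumulated onto the bin
#' nodes. Published defaults: 3 bins at magnification 5.
#'
#' @param table A `localization_table`.
#' @param width_nm,height_nm Field dimensions in nm (defaults to the data
#'   extent padded to full histogram bins).
#' @param n_bins Number of temporal bins (default 3).
#' @param magnification Histogram oversampling relative to `pixel_size_nm`
#'   (default 5).
#' @param pixel_size_nm Camera pixel size in nm (default 100).
#' @param iterations Refinement passes (default 8, with early exit on convergence).
#' @returns A `drift_track`: data.frame with `frame`, `dx_nm`, `dy_nm`
#'   covering the table's full frame range; zero at the first bin midpoint.
#' @export
estimate_drift <- function(table, width_nm = NULL, height_nm = NULL,
                           n_bins = 3, magnification = 5,
                           pixel_size_nm = 100, iterations = 8) {
  stopifnot(n_bins >= 2, iterations >= 1)
  if (nrow(table) < n_bins * 100)
    warning("fewer than ", n_bins * 100,
            " localizations; drift estimate may be unreliable")
  bin_nm <- pixel_size_nm / magnification
  if (is.null(width_nm)) width_nm <- max(table$x_nm) + bin_nm
  if (is.null(height_nm)) height_nm <- max(table$y_nm) + bin_nm
  f0 <- min(table$frame); f1 <- max(table$frame)
  edges <- seq(f0, f1 + 1, length.out = n_bins + 1)
  bin_of <- pmin(n_bins, findInterval(table$frame, edges))
  counts <- tabulate(bin_of, n_bins)
  if (any(counts < 10))
    stop("temporal bin with fewer than 10 localizations")
  mids <- (edges[-length(edges)] + edges[-1] - 1) / 2
  offs <- matrix(0, n_bins, 2) # node offsets relative to bin 1
  for (it in seq_len(iterations)) {
    # subtract current track, extended linearly beyond the outer midpoints
    # so end bins are not artificially smeared during refinement
    dx <- interp_linear(mids, offs[, 1], table$frame)
    dy <- interp_linear(mids, offs[, 2], table$frame)
    hists <- lapply(seq_len(n_bins), function(b) {
      i <- bin_of == b
      render_histogram(table$x_nm[i] - dx[i], table$y_nm[i] - dy[i],
                       width_nm, height_nm, bin_nm)
    })
    delta <- t(vapply(2:n_bins, function(b)
      xcorr_shift(hists[[b]], hists[[1]]) * bin_nm, numeric(2)))
    offs[-1, ] <- offs[-1, , drop = FALSE] + delta
    if (max(abs(delta)) < bin_nm / 100) break
  }
  frames <- f0:f1
  dx <- stats::approx(mids, offs[, 1], xout = frames, rule = 2)$y
  dy <- stats::approx(mids, offs[, 2], xout = frames, rule = 2)$y
  structure(data.frame(frame = frames, dx_nm = dx, dy_nm = dy),
            class = c("drift_track", "data.frame"))
}

# piecewise-linear interpolation with linear extrapolation at both ends
interp_linear <- function(xs, ys, xout) {
  y <- stats::approx(xs, ys, xout = xout, rule = 2)$y
  n <- length(xs)
  lo <- xout < xs[1]
  hi <- xout > xs[n]
  if (any(lo)) {
    s <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    y[lo] <- ys[1] + s * (xout[lo] - xs[1])
  }
  if (any(hi)) {
    s <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    y[hi] <- ys[n] + s * (xout[hi] - xs[n])
  }
  y
}

#' Subtract an estimated drift track from localization coordinates
#'
#' @param table A `localization_table`.
#' @param drift A `drift_track` covering the table's frame range.
#' @returns The corrected `localization_table`.
#' @export
apply_drift <- function(table, drift) {
  idx <- match(table$frame, drift$frame)
  if (any(is.na(idx))) stop("drift track does not cover the frame range")
  table$x_nm <- table$x_nm - drift$dx_nm[idx]
  table$y_nm <- table$y_nm - drift$dy_nm[idx]
  table
}

#' Merge re-blinking events into single molecules
#'
#' Greedy chaining in frame order: an event joins an open chain when it lies
#' within `max_distance_nm` of the chain's anchor (photon-weighted running
#' centroid by default, or the chain's first event with `anchor = "first"`)
#' and within `max_gap_frames` of the chain's last frame. The nearest
#' qualifying chain wins; ties go to the earliest chain. Each chain yields
#' one row: photon-weighted mean position and sigma, summed photons, first
#' frame, combined uncertainty `(sum 1/u_i^2)^(-1/2)`, and `n_merged` the
#' chain length. Published thresholds: 50 nm and 20 frames.
#'
#' @param table A drift-corrected `localization_table`.
#' @param max_distance_nm Capture radius in nm (default 50).
#' @param max_gap_frames Maximum frame gap (default 20).
#' @param anchor `"centroid"` (default) or `"first"`.
#' @returns A merged `localization_table` sorted by frame then x.
#' @export
merge_reblinks <- function(table, max_distance_nm = 50, max_gap_frames = 20,
                           anchor = c("centroid", "first")) {
  anchor <- match.arg(anchor)
  if (!nrow(table)) return(table)
  o <- order(table$frame, table$x_nm)
  tb <- table[o, , drop = FALSE]
  # open chains: anchor position, accumulators
  ax <- numeric(); ay <- numeric(); wsum <- numeric()
  sx <- numeric(); sy <- numeric(); sphot <- numeric(); ssig <- numeric()
  sinvu2 <- numeric(); first_frame <- integer(); last_frame <- integer()
  count <- integer()
  for (i in seq_len(nrow(tb))) {
    x <- tb$x_nm[i]; y <- tb$y_nm[i]; f <- tb$frame[i]
    ph <- tb$photons[i]; sg <- tb$sigma_nm[i]; un <- tb$uncertainty_nm[i]
    open <- which(f - last_frame <= max_gap_frames & f > last_frame)
    best <- 0L
    if (length(open)) {
      d <- sqrt((ax[open] - x)^2 + (ay[open] - y)^2)
      ok <- d <= max_distance_nm
      if (any(ok)) {
        cand <- open[ok]
        best <- cand[which.min(d[ok])] # ties: which.min takes the earliest
      }
    }
    if (best) {
      sx[best] <- sx[best] + ph * x; sy[best] <- sy[best] + ph * y
      sphot[best] <- sphot[best] + ph
      ssig[best] <- ssig[best] + ph * sg
      sinvu2[best] <- sinvu2[best] + 1 / un^2
      last_frame[best] <- f
      count[best] <- count[best] + 1L
      wsum[best] <- wsum[best] + ph
      if (anchor == "centroid") {
        ax[best] <- sx[best] / wsum[best]
        ay[best] <- sy[best] / wsum[best]
      }
    } else {
      ax <- c(ax, x); ay <- c(ay, y); wsum <- c(wsum, ph)
      sx <- c(sx, ph * x); sy <- c(sy, ph * y); sphot <- c(sphot, ph)
      ssig <- c(ssig, ph * sg); sinvu2 <- c(sinvu2, 1 / un^2)
      first_frame <- c(first_frame, f); last_frame <- c(last_frame, f)
      count <- c(count, 1L)
    }
  }
  out <- localization_table(frame = first_frame, x_nm = sx / sphot,
                            y_nm = sy / sphot, sigma_nm = ssig / sphot,
                            photons = sphot,
                            uncertainty_nm = 1 / sqrt(sinvu2),
                            n_merged = count)
  out <- out[order(out$frame, out$x_nm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("localization_table", "data.frame")
  out
}
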