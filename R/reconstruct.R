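# Separable convolution with mirrored boundaries, used by the a-trous
# B-spline decomposition. kernel is a centred odd-length vector.
sepconv_mirror <- function(img, kernel) {
  half <- (length(kernel) - 1) / 2
  mirror_idx <- function(i, n) {
    # reflect without repeating the edge sample: 0 -> 2, n+1 -> n-1
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- 0 * m
    for (k in seq_along(kernel)) {
      off <- k - half - 1
      idx <- mirror_idx(seq_len(n) + off, n)
      out <- out + kernel[k] *
        (if (along_rows) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(img, TRUE), FALSE)
}

#' A-trous B-spline wavelet decomposition of a frame
#'
#' Order-3 B-spline kernel `k = c(1, 4, 6, 4, 1) / 16` applied separably:
#' `V1 = k * V0`; `V2 = k2 * V1` with `k2` the kernel dilated by inserting
#' one zero between taps; detail planes `F1 = V0 - V1`, `F2 = V1 - V2`.
#' Boundaries are mirrored. F2 carries blinking-event-scale structure and is
#' the plane peaks are detected on; the noise level is estimated from F1.
#'
#' @param frame Numeric matrix (photons), at least 8 x 8.
#' @returns List of class `wavelet_planes` with `F1`, `F2`, `V1`, `V2` and
#'   the input `V0`.
#' @export
wavelet_filter <- function(frame) {
  stopifnot(is.matrix(frame))
  if (nrow(frame) < 8 || ncol(frame) < 8) stop("frame must be at least 8x8")
  if (any(!is.finite(frame))) stop("non-finite pixels in frame")
  k1 <- c(1, 4, 6, 4, 1) / 16
  k2 <- c(1, 0, 4, 0, 6, 0, 4, 0, 1) / 16
  v1 <- sepconv_mirror(frame, k1)
  v2 <- sepconv_mirror(v1, k2)
  structure(list(F1 = frame - v1, F2 = v1 - v2, V1 = v1, V2 = v2,
                 V0 = frame),
            class = "wavelet_planes")
}

#' Detect candidate emitters on the F2 wavelet plane
#'
#' Candidates are pixels of F2 that exceed `threshold_multiplier` times the
#' standard deviation of the F1 plane and are maxima over their
#' 8-neighbourhood. Plateaus of equal value count once, keeping the
#' row-major first pixel.
#'
#' @param planes A `wavelet_planes` object.
#' @param threshold_multiplier Threshold in F1 standard deviations
#'   (default 2).
#' @returns Integer matrix with columns `row`, `col` (1-based pixel
#'   positions).
#' @export
detect_peaks <- function(planes, threshold_multiplier = 2) {
  stopifnot(inherits(planes, "wavelet_planes"))
  f2 <- planes$F2
  thr <- threshold_multiplier * sd(planes$F1)
  nr <- nrow(f2); nc <- ncol(f2)
  above <- f2 > thr
  # not exceeded by any 8-neighbour
  is_max <- above
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(-Inf, nr, nc)
    ri <- max(1, 1 + di):min(nr, nr + di)
    ci <- max(1, 1 + dj):min(nc, nc + dj)
    shifted[ri, ci] <- f2[ri - di, ci - dj]
    is_max <- is_max & (f2 >= shifted)
  }
  if (!any(is_max)) return(cbind(row = integer(), col = integer()))
  # collapse 8-connected equal-valued plateaus to their row-major first pixel
  lab <- cpp_label8(is_max)
  cand <- which(is_max, arr.ind = TRUE)
  o <- order(cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  labs <- lab[cand]
  keep <- !duplicated(labs)
  out <- cand[keep, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

# Poisson negative log-likelihood of the integrated-Gaussian emitter model
# over a square window. par = (x, y, N, b, sigma) in pixel units, window
# coordinates with pixel centres at (k - 0.5).
emitter_nll <- function(par, counts) {
  n <- nrow(counts)
  xe <- 0:n
  fx <- diff(pnorm(xe, par[1], par[5]))
  fy <- diff(pnorm(xe, par[2], par[5]))
  mu <- par[3] * (fy %o% fx) + par[4]
  mu <- pmax(mu, 1e-12)
  sum(mu - counts * log(mu))
}

#' Fit one emitter with an integrated-Gaussian Poisson MLE
#'
#' Maximum-likelihood fit of the model
#' `mu_uv = N [Phi((u+1-x)/s) - Phi((u-x)/s)] [Phi((v+1-y)/s) - Phi((v-y)/s)] + b`
#' over the `(2 r + 1)^2` pixel window centred on the candidate. The
#' lateral uncertainty reported is the Mortensen-style MLE approximation
#' `var(x) = (s_a^2 / N) (16/9 + 8 pi s_a^2 b / (N a^2))` with
#' `s_a^2 = s^2 + a^2 / 12` and `a` the pixel size.
#'
#' @param frame Numeric matrix (photons).
#' @param candidate Integer `c(row, col)` of the candidate pixel.
#' @param pixel_size_nm Pixel size in nm.
#' @param frame_index Frame number recorded on the output row.
#' @param fit_radius_px Half-width of the fitting window (default 5).
#' @param sigma0_px Initial PSF sigma in pixels (default 1.6).
#' @returns A one-row `localization_table`, or `NULL` when the fit fails
#'   the validity bounds (sigma outside (0.3, 10) px or non-convergence).
#' @export
fit_emitter <- function(frame, candidate, pixel_size_nm = 100,
                        frame_index = 1L, fit_radius_px = 5,
                        sigma0_px = 1.6) {
  r <- fit_radius_px
  ci <- candidate[1]; cj <- candidate[2]
  if (ci <= r || cj <= r || ci > nrow(frame) - r || cj > ncol(frame) - r)
    stop("candidate closer than fit_radius to the border")
  win <- frame[(ci - r):(ci + r), (cj - r):(cj + r)]
  n <- 2 * r + 1
  b0 <- max(min(win), 1e-3)
  n0 <- max(sum(win) - b0 * n^2, 10)
  # window coordinates: x along columns, y along rows, centre of candidate
  # pixel at (r + 0.5, r + 0.5)
  par0 <- c(r + 0.5, r + 0.5, n0, b0, sigma0_px)
  fit <- tryCatch(
    optim(par0, emitter_nll, counts = win, method = "L-BFGS-B",
          lower = c(0.5, 0.5, 1, 1e-6, 0.2),
          upper = c(n - 0.5, n - 0.5, Inf, Inf, 12),
          control = list(maxit = 200, factr = 1e5)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(NULL)
  p <- fit$par
  if (p[5] <= 0.3 || p[5] >= 10) return(NULL)
  a <- pixel_size_nm
  sa2 <- (p[5]^2 + 1 / 12) * a^2
  unc <- sqrt(sa2 / p[3] * (16 / 9 + 8 * pi * sa2 * p[4] / (p[3] * a^2)))
  # window origin (left edge of first window pixel) in field coordinates
  x_nm <- (cj - r - 1 + p[1]) * a
  y_nm <- (ci - r - 1 + p[2]) * a
  localization_table(frame = frame_index, x_nm = x_nm, y_nm = y_nm,
                     sigma_nm = p[5] * a, photons = p[3],
                     uncertainty_nm = unc)
}

#' Reconstruct a localization table from a raw movie
#'
#' Per frame: wavelet filtering, peak detection on F2 at
#' `threshold_multiplier` standard deviations of F1, duplicate suppression
#' (candidates closer than the fit radius keep only the brighter one),
#' integrated-Gaussian Poisson MLE fitting. Output rows are sorted by frame
#' then x.
#'
#' @param movie A `raw_movie`.
#' @param threshold_multiplier Detection threshold (default 2).
#' @param fit_radius_px Fitting window half-width (default 5).
#' @param sigma0_px Initial sigma in pixels (default 1.6).
#' @param verbose Log per-stage counts.
#' @returns A `localization_table`.
#' @export
reconstruct_movie <- function(movie, threshold_multiplier = 2,
                              fit_radius_px = 5, sigma0_px = 1.6,
                              verbose = FALSE) {
  stopifnot(inherits(movie, "raw_movie"))
  n_frames <- dim(movie$frames)[1]
  n_cand <- 0L; n_dropped <- 0L
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    frame <- movie$frames[f, , ]
    planes <- wavelet_filter(frame)
    cand <- detect_peaks(planes, threshold_multiplier)
    # keep only candidates far enough from the border to fit
    r <- fit_radius_px
    ok <- cand[, 1] > r & cand[, 2] > r &
      cand[, 1] <= nrow(frame) - r & cand[, 2] <= ncol(frame) - r
    cand <- cand[ok, , drop = FALSE]
    cand <- suppress_duplicates(cand, planes$F2, fit_radius_px)
    n_cand <- n_cand + nrow(cand)
    fits <- lapply(seq_len(nrow(cand)), function(i)
      fit_emitter(frame, cand[i, ], movie$pixel_size_nm, f,
                  fit_radius_px, sigma0_px))
    n_dropped <- n_dropped + sum(vapply(fits, is.null, logical(1)))
    fits <- Filter(Negate(is.null), fits)
    if (length(fits)) rows[[f]] <- do.call(rbind, fits)
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- localization_table()
  out <- out[order(out$frame, out$x_nm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("localization_table", "data.frame")
  if (verbose)
    message(sprintf("reconstruct: %d candidates, %d dropped, %d localized",
                    n_cand, n_dropped, nrow(out)))
  out
}

# candidates closer than min_dist_px keep only the brighter (F2 value)
suppress_duplicates <- function(cand, f2, min_dist_px) {
  if (nrow(cand) < 2) return(cand)
  vals <- f2[cand]
  o <- order(-vals)
  keep <- logical(nrow(cand))
  for (i in o) {
    ok <- TRUE
    for (j in which(keep)) {
      if (max(abs(cand[i, ] - cand[j, ])) == 0) next
      if (sqrt(sum((cand[i, ] - cand[j, ])^2)) < min_dist_px) {
        ok <- FALSE; break
      }
    }
    if (ok) keep[i] <- TRUE
  }
  cand[sort(which(keep)), , drop = FALSE]
}
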