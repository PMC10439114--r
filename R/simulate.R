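#' Simulate complete spatial randomness (homogeneous Poisson process)
#'
#' The null model against which clustering statistics are calibrated: the
#' number of points is Poisson(density x area) and positions are uniform
#' over the region.
#'
#' @param width_um,height_um Region dimensions in micrometres.
#' @param density_per_um2 Intensity in localizations per square micrometre.
#' @param seed Integer RNG seed.
#' @returns A [point_pattern()] (coordinates in nm).
#' @export
simulate_csr <- function(width_um, height_um, density_per_um2, seed = 1) {
  if (width_um <= 0 || height_um <= 0) stop("zero-area region")
  stopifnot(density_per_um2 > 0)
  set.seed(seed)
  n <- rpois(1, density_per_um2 * width_um * height_um)
  point_pattern(runif(n, 0, width_um * 1000), runif(n, 0, height_um * 1000),
                width_um * 1000, height_um * 1000)
}

#' Simulate a Thomas (Neyman-Scott) cluster process
#'
#' Poisson parents of intensity `kappa` per square micrometre; each parent
#' receives Poisson(`mu`) offspring scattered isotropically
#' Normal(0, `sigma_nm`^2) per axis. Offspring are wrapped toroidally into
#' the region so the closed-form Ripley K,
#' `K(r) = pi r^2 + (1/kappa) (1 - exp(-r^2 / (4 sigma^2)))`,
#' holds exactly under toroidal distances. Emulates the dense sub-micron
#' receptor nanoclusters that ligation induces at the immune synapse.
#'
#' @param kappa Parent intensity per square micrometre.
#' @param mu Mean offspring per parent.
#' @param sigma_nm Gaussian cluster scatter in nm.
#' @param width_um,height_um Region dimensions in micrometres.
#' @param seed Integer RNG seed.
#' @returns A [point_pattern()] with attribute `parents` (data.frame of
#'   parent centres in nm).
#' @export
simulate_thomas <- function(kappa, mu, sigma_nm, width_um, height_um,
                            seed = 1) {
  stopifnot(kappa > 0, mu > 0, sigma_nm >= 0,
            width_um > 0, height_um > 0)
  set.seed(seed)
  w <- width_um * 1000; h <- height_um * 1000
  n_par <- rpois(1, kappa * width_um * height_um)
  px <- runif(n_par, 0, w); py <- runif(n_par, 0, h)
  n_off <- rpois(n_par, mu)
  parent_id <- rep.int(seq_len(n_par), n_off)
  x <- (px[parent_id] + rnorm(sum(n_off), 0, sigma_nm)) %% w
  y <- (py[parent_id] + rnorm(sum(n_off), 0, sigma_nm)) %% h
  p <- point_pattern(x, y, w, h)
  attr(p, "parents") <- data.frame(x = px, y = py)
  attr(p, "parent_id") <- parent_id
  p
}

#' Closed-form Ripley K of the Thomas process
#' @param r Radii in nm.
#' @param kappa Parent intensity per square micrometre.
#' @param sigma_nm Cluster scatter in nm.
#' @returns K(r) in nm^2.
#' @export
thomas_k_theoretical <- function(r, kappa, sigma_nm) {
  pi * r^2 + (1e6 / kappa) * (1 - exp(-r^2 / (4 * sigma_nm^2)))
}

#' Simulate a two-channel pattern with a known colocalized fraction
#'
#' Channel A is a Thomas process. A fraction `coloc_fraction` of A's cluster
#' centres is reused for channel B, displaced by Normal(0, `offset_nm`^2)
#' per axis; the remaining B clusters are placed independently. The
#' ground-truth pairing of shared parents is recorded, giving known truth
#' for nanoscale cross-channel proximity analyses.
#'
#' @param params List with `kappa`, `mu`, `sigma_nm` for both channels.
#' @param coloc_fraction Fraction of B cluster centres shared with A, in
#'   \[0, 1\].
#' @param offset_nm SD of the displacement applied to shared centres.
#' @param width_um,height_um Region in micrometres.
#' @param seed Integer RNG seed.
#' @returns List with `A`, `B` (point patterns) and `pairing` (data.frame of
#'   shared parent centres in both channels).
#' @export
simulate_two_channel <- function(params = list(kappa = 4, mu = 25,
                                               sigma_nm = 50),
                                 coloc_fraction = 0.5, offset_nm = 20,
                                 width_um = 5, height_um = 5, seed = 1) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1)
  set.seed(seed)
  w <- width_um * 1000; h <- height_um * 1000
  area <- width_um * height_um
  scatter <- function(px, py) {
    n_off <- rpois(length(px), params$mu)
    id <- rep.int(seq_along(px), n_off)
    list(x = (px[id] + rnorm(sum(n_off), 0, params$sigma_nm)) %% w,
         y = (py[id] + rnorm(sum(n_off), 0, params$sigma_nm)) %% h)
  }
  n_par <- rpois(1, params$kappa * area)
  ax <- runif(n_par, 0, w); ay <- runif(n_par, 0, h)
  n_shared <- rbinom(1, n_par, coloc_fraction)
  shared <- if (n_par) sample.int(n_par, n_shared) else integer()
  bx_shared <- (ax[shared] + rnorm(n_shared, 0, offset_nm)) %% w
  by_shared <- (ay[shared] + rnorm(n_shared, 0, offset_nm)) %% h
  n_indep <- n_par - n_shared
  bx <- c(bx_shared, runif(n_indep, 0, w))
  by <- c(by_shared, runif(n_indep, 0, h))
  offA <- scatter(ax, ay)
  offB <- scatter(bx, by)
  A <- point_pattern(offA$x, offA$y, w, h)
  B <- point_pattern(offB$x, offB$y, w, h)
  attr(A, "parents") <- data.frame(x = ax, y = ay)
  attr(B, "parents") <- data.frame(x = bx, y = by)
  list(A = A, B = B,
       pairing = data.frame(ax = ax[shared], ay = ay[shared],
                            bx = bx_shared, by = by_shared))
}

#' Simulate stochastic on/off emitter state tracks
#'
#' On-times and dark gaps are geometric runs; an emitter bleaches after a
#' geometric number of blinks. A convenience for building re-blinking
#' ground truth; tests that need exact state control construct the state
#' matrix directly.
#'
#' @param n_emitters,n_frames Dimensions of the state matrix.
#' @param mean_on,mean_dark Mean run lengths in frames.
#' @param mean_blinks Mean number of on-runs before bleaching.
#' @param seed Integer RNG seed.
#' @returns Logical matrix `n_frames x n_emitters`.
#' @export
simulate_emitter_states <- function(n_emitters, n_frames, mean_on = 3,
                                    mean_dark = 30, mean_blinks = 2,
                                    seed = 1) {
  set.seed(seed)
  on <- matrix(FALSE, n_frames, n_emitters)
  for (e in seq_len(n_emitters)) {
    f <- 1 + rgeom_safe(mean_dark)
    blinks <- 1 + rgeom_safe(mean_blinks - 1)
    for (b in seq_len(blinks)) {
      len <- 1 + rgeom_safe(mean_on - 1)
      if (f > n_frames) break
      on[f:min(n_frames, f + len - 1), e] <- TRUE
      f <- f + len + 1 + rgeom_safe(mean_dark)
    }
  }
  on
}

rgeom_safe <- function(mean) {
  if (mean <= 0) return(0L)
  stats::rgeom(1, 1 / (1 + mean))
}

#' Render a blinking-emitter movie with known ground truth
#'
#' Each emitter that is on in a frame contributes an integrated 2-D Gaussian
#' PSF (per-pixel erf differences) scaled to its photon count, on a constant
#' photon background, with optional per-pixel Poisson noise. A drift track
#' (nm per frame) is added to all emitter positions.
#'
#' @param x_nm,y_nm True emitter positions (nm).
#' @param on Logical matrix `n_frames x n_emitters` of on-states.
#' @param photons Photons emitted per on-frame (scalar or per-emitter).
#' @param field_px Field size `c(rows, cols)` in pixels.
#' @param pixel_size_nm Pixel size in nm.
#' @param psf_sigma_nm PSF standard deviation in nm.
#' @param background_photons Background photons per pixel per frame.
#' @param drift_nm Optional `n_frames x 2` matrix of (dx, dy) drift in nm.
#' @param poisson_noise Apply per-pixel Poisson noise (default `TRUE`).
#' @param seed Integer RNG seed.
#' @returns A `raw_movie` with attribute `ground_truth` (list of the inputs).
#' @export
simulate_blink_movie <- function(x_nm, y_nm, on, photons = 2000,
                                 field_px = c(32, 32), pixel_size_nm = 100,
                                 psf_sigma_nm = 160, background_photons = 0,
                                 drift_nm = NULL, poisson_noise = TRUE,
                                 seed = 1) {
  stopifnot(psf_sigma_nm > 0, length(x_nm) == length(y_nm))
  n_frames <- nrow(on)
  n_em <- length(x_nm)
  stopifnot(ncol(on) == n_em)
  if (length(photons) == 1) photons <- rep(photons, n_em)
  if (is.null(drift_nm)) drift_nm <- matrix(0, n_frames, 2)
  set.seed(seed)
  w_nm <- field_px[2] * pixel_size_nm; h_nm <- field_px[1] * pixel_size_nm
  inside <- x_nm >= 0 & x_nm < w_nm & y_nm >= 0 & y_nm < h_nm
  if (any(!inside)) {
    warning(sum(!inside), " emitter(s) outside field skipped")
  }
  frames <- array(0, dim = c(n_frames, field_px[1], field_px[2]))
  # pixel edge coordinates in nm
  xe <- (0:field_px[2]) * pixel_size_nm
  ye <- (0:field_px[1]) * pixel_size_nm
  for (f in seq_len(n_frames)) {
    img <- matrix(background_photons, field_px[1], field_px[2])
    for (e in which(on[f, ] & inside)) {
      ex <- x_nm[e] + drift_nm[f, 1]
      ey <- y_nm[e] + drift_nm[f, 2]
      fx <- diff(pnorm(xe, ex, psf_sigma_nm))
      fy <- diff(pnorm(ye, ey, psf_sigma_nm))
      img <- img + photons[e] * (fy %o% fx)
    }
    if (poisson_noise) img[] <- rpois(length(img), img)
    frames[f, , ] <- img
  }
  mv <- structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                       camera_offset = 0, counts_per_photon = 1),
                  class = "raw_movie")
  attr(mv, "ground_truth") <- list(x_nm = x_nm, y_nm = y_nm, on = on,
                                   photons = photons, drift_nm = drift_nm)
  mv
}

#' Simulate a normalized FRAP recovery trace
#'
#' Single-exponential recovery with an immobile fraction:
#' `I(t) = M (1 - 2^(-t / t_half))` for time `t` after the bleach, with
#' additive Gaussian noise; pre-bleach samples are 1.
#'
#' @param t_half_s Recovery half-time in seconds.
#' @param mobile_fraction Mobile fraction `M` in (0, 1\].
#' @param noise_sd Additive Gaussian noise SD.
#' @param duration_s Post-bleach duration in seconds.
#' @param dt_s Sampling interval in seconds.
#' @param bleach_time_s Time of the bleach on the absolute clock.
#' @param seed Integer RNG seed.
#' @returns List of class `frap_trace` with `time_s`, `intensity`,
#'   `bleach_time_s`.
#' @export
simulate_frap_trace <- function(t_half_s, mobile_fraction = 0.9,
                                noise_sd = 0, duration_s = 300, dt_s = 1,
                                bleach_time_s = 10, seed = 1) {
  stopifnot(t_half_s > 0, mobile_fraction > 0, mobile_fraction <= 1)
  set.seed(seed)
  t_pre <- seq(0, bleach_time_s - dt_s, by = dt_s)
  t_post <- seq(0, duration_s, by = dt_s)
  i_post <- mobile_fraction * (1 - 2^(-t_post / t_half_s)) +
    rnorm(length(t_post), 0, noise_sd)
  structure(list(time_s = c(t_pre, bleach_time_s + t_post),
                 intensity = pmin(pmax(c(rep(1, length(t_pre)), i_post),
                                       -0.2), 1.5),
                 bleach_time_s = bleach_time_s),
            class = "frap_trace")
}

#' Simulate a synapse image with a known bright clustered-pixel fraction
#'
#' Inside the cell mask, an exact fraction of pixels is set to
#' `contrast x base` and the rest to `base`, so the clustering index of the
#' result is the bright fraction by construction (for moderate fractions).
#'
#' @param shape `c(rows, cols)` of the image.
#' @param cell_mask Logical matrix; defaults to the whole image.
#' @param bright_fraction Fraction of masked pixels made bright, in \[0, 1).
#' @param contrast Bright/base intensity ratio (> 1.5).
#' @param base Base intensity.
#' @param seed Integer RNG seed.
#' @returns A [pixel_image()] with attribute `bright_index` (indices of the
#'   ground-truth bright pixels).
#' @export
simulate_synapse_image <- function(shape = c(64, 64), cell_mask = NULL,
                                   bright_fraction = 0.1, contrast = 10,
                                   base = 100, seed = 1) {
  stopifnot(bright_fraction >= 0, bright_fraction < 1, contrast > 1.5)
  set.seed(seed)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, shape[1], shape[2])
  vals <- matrix(base, nrow(cell_mask), ncol(cell_mask))
  idx <- which(cell_mask)
  n_bright <- round(bright_fraction * length(idx))
  bright <- if (n_bright) sample(idx, n_bright) else integer()
  vals[bright] <- contrast * base
  img <- pixel_image(vals, mask = cell_mask)
  attr(img, "bright_index") <- sort(bright)
  img
}
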