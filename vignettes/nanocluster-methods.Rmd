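---
title: "Quantifying receptor nanoclusters: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor nanoclusters: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocluster)
```

# Scope

`nanocluster` implements a complete quantitative pipeline for
single-molecule localization microscopy (dSTORM) of membrane receptors at
the immune synapse: reconstruction of blinking-emitter movies into
localization tables, the standard post-processing chain (quality filtering,
drift correction, re-blink merging), second-order spatial statistics
(Ripley K/L/H), local cluster segmentation (Getis–Franklin), two-channel
colocalization (coordinate-based colocalization, nearest-neighbour
distances, Voronoi tessellation correlations), and diffraction-limited
pixel metrics (clustering index, synaptic enrichment, FRAP kinetics).
Because this class of study rarely deposits raw imaging data, the package
ships first-class synthetic-data generators with known ground truth; every
statistical claim the test suite makes is made against those generators or
against closed-form oracles.

# Units and conventions

All coordinates, PSF sigmas and localization uncertainties are in
nanometres; intensities are photons; densities are localizations per
square micrometre. Camera-pixel units appear only inside the
reconstruction stage. The field origin is the top-left corner, x runs
along columns, y along rows; pixel centres sit at $(k + 0.5)\,a$ for pixel
size $a$; analysis regions are half-open $[x_0, x_1) \times [y_0, y_1)$,
which makes cropping and area arithmetic unambiguous. The default pixel
size is 100 nm (a 160x objective on 16-micron EMCCD pixels); it is a
configuration key, not a constant.

# Reconstruction

**Detection.** Each frame is decomposed with the à-trous B-spline wavelet
(order 3, scale 2): the kernel $k = [1,4,6,4,1]/16$ is applied separably
to give $V_1$, then once more with one zero inserted between taps to give
$V_2$; the detail planes are $F_1 = V_0 - V_1$ and $F_2 = V_1 - V_2$, with
mirrored boundaries. Candidates are pixels of $F_2$ exceeding
`threshold_multiplier` (default 2) times the standard deviation of $F_1$
that are maxima over their 8-neighbourhood; equal-valued plateaus count
once, keeping the row-major first pixel. We threshold and search on $F_2$
and measure noise on $F_1$ — the two planes play different roles and the
processing recipe the pipeline follows names both; this split matches the
convention of the widely used reconstruction software this stage is
compatible with. Candidates closer than the fit radius keep only the
brighter one, so one molecule is never fitted twice.

**Fitting.** Each candidate window ($11 \times 11$ pixels by default) is
fitted by maximum likelihood under Poisson noise with the integrated
Gaussian PSF model
$$\mu_{uv} = N\,[\Phi(\tfrac{u+1-x}{\sigma}) - \Phi(\tfrac{u-x}{\sigma})]
             [\Phi(\tfrac{v+1-y}{\sigma}) - \Phi(\tfrac{v-y}{\sigma})] + b,$$
with photon count $N$, background $b$ per pixel and PSF width $\sigma$,
starting from $\sigma_0 = 1.6$ px. The optimizer is box-constrained
quasi-Newton (L-BFGS-B) on the natural parameters — deterministic given
the input, which the pipeline's reproducibility contract requires. Fits
with $\sigma$ outside $(0.3, 10)$ px or failed convergence are dropped and
counted. The reported lateral uncertainty is the Mortensen-style MLE
approximation
$$\sigma_\text{loc}^2 = \frac{\sigma_a^2}{N}
  \left(\frac{16}{9} + \frac{8\pi \sigma_a^2 b}{N a^2}\right),
  \qquad \sigma_a^2 = \sigma^2 + a^2/12 .$$
The filtering stage consumes this number, so its definition is fixed and
documented rather than left implicit. On simulated single emitters the
empirical scatter of fitted positions tracks this estimate within 25%
for $N \in \{500, 1000, 5000\}$ photons.

# Post-processing

**Quality filter.** Events are retained when photons $> 600$ (strict),
$\sigma \in [50, 200]$ nm (closed interval — the recipe leaves
inclusivity unstated; we chose closed and log the choice), and uncertainty
$< 30$ nm (strict).

**Drift correction.** Frames are split into 3 equal temporal bins, each
rendered as a 2-D histogram at bin size `pixel_size / 5`; bin k is
cross-correlated against bin 1 (FFT, 3x3 parabolic sub-bin peak) and
per-frame drift is linearly interpolated between bin midpoints with
constant extrapolation at the ends, zero at the first bin midpoint. A
drift of 0.5 nm/frame smears each 1000-frame bin by 500 nm, which limits a
single correlation pass to tens of nanometres; the estimator therefore
iterates — subtract the current track (extended linearly at the ends
*during refinement only*), re-render the now-sharp bins, and accumulate
the residual offsets — until the update falls below 1/100 histogram bin
(at most 8 passes). Iterative residual correction is standard in SMLM
drift estimation; with it, a 0.5 nm/frame linear drift on a 2,000-event
clustered simulation is recovered to a few nanometres at the track
endpoint.

**Re-blink merging.** Events within 50 nm and 20 frames are chained
greedily in frame order. The anchor is the chain's photon-weighted running
centroid (`anchor = "centroid"`); the alternative `"first"` anchors on the
initial detection, which the recipe's wording equally supports — the
centroid is the default because early low-photon fits would otherwise
misplace the anchor. A merged molecule keeps the photon-weighted mean
position and sigma, summed photons, first frame, inverse-variance-combined
uncertainty $(\sum u_i^{-2})^{-1/2}$ (a standard estimator; the recipe is
silent) and the chain length as `n_merged`. Merging conserves total
photons and is idempotent because the gap rule acts on first frames.

# Cluster statistics

**Ripley curves.** $\hat K(r) = \frac{|A|}{n(n-1)} \sum_{i \ne j}
\mathbf 1(d_{ij} \le r)$, $L = \sqrt{K/\pi}$, $H = L - r$. Inside cropped
5x5 or 3x3 micron analysis regions the default is *no* edge correction:
the negative bias is shared across compared conditions, matching how the
statistic is used comparatively, and the processing recipe names no
correction. The toroidal mode exists so that the Thomas-process closed
form (below) is an exact oracle. The radius grid default is 10–500 nm in
10-nm steps, resolving reported peak radii from ~40 nm (unligated
receptor) to ~430 nm (ligated); for 3x3 micron regions a 10–300 nm grid is
appropriate. The H peak is the grid argmax, smallest radius on ties, and a
pattern with $H \le 0$ everywhere reports the no-clustering sentinel
(`NA`).

**Getis–Franklin maps.** Per point,
$L_i(r) = \sqrt{|A| \sum_{j \ne i} \mathbf 1(d_{ij} \le r) / (\pi (n-1))}$
at `r_local = 50` nm. For the density map, the scattered $L_i$ values are
interpolated by inverse-distance weighting over points within `r_local` of
each grid cell centre (default 5-nm grid), cells farther than `r_local`
from every point set to 0. Scattered *linear* interpolation would need a
triangulation; IDW with the same support radius preserves the two
properties the downstream segmentation uses — exact values at the points
and compact support — and is the package's documented interpolation
choice. Note that for sparse patterns the *mean* of $L_i$ under CSR sits
below $r$ (the square root is concave; only $E[L_i^2] = r^2$ is exact), so
null calibration is done by simulation, not by comparing means to $r$.

**Segmentation and metrics.** The binary-map threshold is the 99th
percentile of $L_i$ pooled over 100 CSR simulations matched to the
pattern's n and region; 8-connected components of at least 3 grid cells
become clusters. Cluster area is the thresholded-map area, which includes
the `r_local` smoothing halo — absolute areas are therefore comparable
only within a fixed parameter set, and the tests assert the halo
explicitly (a 200-nm disc of points segments to roughly the area of the
disc dilated by `r_local`). Reported metrics per region: overall density,
mean cluster area, in-cluster density, number of clusters, and fraction of
events in clusters. Under CSR the median fraction in clusters stays below
0.05 by construction of the threshold. Peaks and metrics are extracted per
region and then summarized across regions, not the other way round.

# Colocalization

**CBC.** For each localization $a$ of channel A, the normalized
neighbour-density profiles over the radius grid $r_k = k\,r_\max/20$
(default $r_\max = 500$ nm, spanning the observed cluster scales)
$$D_{AA}(r_k) = \frac{N_A(a, r_k)}{N_A(a, r_\max)}\,\frac{r_\max^2}{r_k^2},
\qquad D_{AB}(r_k) \text{ likewise with B-neighbours}$$
are Spearman-rank-correlated and damped by the nearest-B distance:
$C_a = S_a e^{-d(a, B)/r_\max} \in [-1, 1]$. Profiles without variance (or
isolated points with no neighbours at $r_\max$) score 0. Neighbour counts
exclude zero-distance partners in both directions, so a channel compared
with an identical copy of itself scores exactly 1 — the behaviour a
self-colocalization control must have. The per-cell summary is the
fraction of scores above 0.8, the conventional "strongly colocalized"
cut-off. The independent-CSR null has a small positive bias (~0.08 at
5x5 microns, 100/µm²) from shared boundary depression of both profiles; it
is a known property of the score near edges, stated here so users compare
conditions rather than absolute values.

**NND.** Exact nearest-neighbour distances from A to B (cell-list
accelerated, identical to brute force), histogrammed in 10-nm bins; the
modal bin centre matches the "peaks at" phrasing used for this statistic.
For independent CSR with target density $\rho$, the distance law is
$p(d) = 2\pi\rho d\,e^{-\pi\rho d^2}$ with mode $1/\sqrt{2\pi\rho}$ — a
closed-form check the tests use.

**Negative control.** "Reversing" localization coordinates is interpreted
as reflection through the region centre ($x \mapsto x_\max + x_\min - x$,
likewise y): an involution that preserves count and intra-channel
structure — the stated purpose of the matched negative control — while
destroying cross-channel registration. The alternative reading
(`mode = "shuffle-pairing"`: re-pair the x list with the reversed y list)
is also implemented.

**Tessellation.** Voronoi cells are clipped to the region (exact
incremental half-plane clipping; unbounded cells become boundary-clipped
polygons) and each point's first-rank density is its inverse cell area.
Both channels' densities are evaluated at every localization of A ∪ B
(whether the original analysis used A only or A ∪ B is not recoverable;
A ∪ B treats the channels symmetrically and is logged), and their Spearman
correlation is the co-organization score. For Mander's-style overlap each
channel's object mask is the union of its cells with density at least
`seg_factor = 2` times the channel mean; $M_A$ is the fraction of A inside
B's mask, symmetrically for $M_B$. Exactly degenerate (collinear or
duplicated) inputs are jittered by 0.01 nm with a warning.

# Pixel metrics

**Clustering index.** Per cell: mean intensity over the cell's ROI mask
(per-cell, to absorb heterogeneous expression), threshold $1.5\times$ that
mean, index = fraction of masked pixels strictly above threshold. The
relative threshold makes the index invariant to intensity scaling.

**Synaptic enrichment.** $\log_2$ of the ratio of background-subtracted
mean intensities in an explicit synapse mask versus an explicit reference
(non-synapse membrane) mask; background is the 5th percentile of the whole
image by default. The reference region is a required input, not inferred —
absolute enrichment values depend on it, and a 4-fold synaptic increase
corresponds to $\log_2$FC = 2 by arithmetic.

**FRAP.** Traces are assumed pre-normalized (bleach-depth and acquisition
bleaching corrected against an unbleached reference, pre-bleach = 1). The
model is single-exponential recovery with an immobile fraction,
$I(t) = M(1 - 2^{-t/t_{1/2}})$ for time $t$ after the bleach — the
quantities reported for this assay are a half-time and a plateau, which
this two-parameter model captures; no diffusion-reaction model is
attempted. Fitting is Levenberg–Marquardt least squares with a
deterministic multi-start over $t_{1/2} \in \{1, 10, 100\}$ s, covering
the two decades between fast ligand recovery (~15 s) and slow receptor
recovery (~115 s). At zero noise both are recovered within 1%; at noise
SD 0.05 the median half-time error is below 10%.

# Synthetic data: what it emulates, and what it does not

* `simulate_csr` — homogeneous Poisson patterns, the null for every
  clustering statistic.
* `simulate_thomas` — Poisson(κ) parents with Poisson(µ) offspring
  scattered Normal(0, σ²) per axis, *toroidally wrapped* so
  $K(r) = \pi r^2 + \kappa^{-1}(1 - e^{-r^2/4\sigma^2})$ holds exactly —
  the analytic oracle for the Ripley estimator. Canonical test conditions
  κ = 4/µm², µ = 25, σ = 50 nm on 5x5 µm give ~100 localizations/µm², the
  density scale of the ligated-receptor regime.
* `simulate_two_channel` — channel B reuses a chosen fraction of A's
  cluster centres (displaced by a Normal offset), giving ground-truth
  colocalization for the discrimination tests.
* `simulate_blink_movie` — integrated-Gaussian PSFs, constant background,
  per-pixel Poisson noise, explicit on/off state matrices and an injected
  drift track. No EMCCD excess noise, no astigmatism, no dye photophysics
  beyond on/off: recovery results on these movies bound estimator quality
  under ideal camera statistics, not under every real-camera pathology.
* `simulate_frap_trace` / `simulate_synapse_image` — the closed-form
  recovery model above, and flat images with an exact bright-pixel
  fraction (so the clustering index has integer-exact ground truth).

Passing tests on these generators demonstrates estimator correctness and
calibration under the stated models; they do not certify behaviour under
structured real-world nuisance (sCMOS fixed-pattern noise, chromatic
offsets between channels, non-Gaussian PSF tails).

# Problem sizes and numerical choices

The test suite and the acceptance script run 50-seed batches of 5x5 µm
patterns at ~2,500 points (Ripley/Getis), 3x3 µm two-channel simulations
at ~900 points per channel (colocalization), a 50-emitter / 25-frame /
90x90 px blinking movie (reconstruction), and 2,000-event / 3,000-frame
drifted tables (drift) — sizes chosen to match the study's reported
region and density scales while keeping a full run in minutes on one CPU.
Other fixed numerical choices: likelihood convergence at relative change
$10^{-8}$ (at most 200 iterations); detection ties resolved row-major;
merging ties to the earliest chain; H-peak ties to the smallest radius;
Getis grid cells beyond `r_local` of any point set to zero; Voronoi
degeneracy jitter 0.01 nm.

# Known limitations

* No 3-D or multi-emitter fitting; overlapping emitters bias fits, and the
  benchmarks keep emitters separated accordingly.
* Cluster areas include the `r_local` halo and depend on the grid step;
  compare only within one parameter set.
* The CBC null bias near edges (above) makes small positive mean scores
  expected for finite regions.
* Drift correction assumes a drift that is well approximated as piecewise
  linear across 3 temporal bins; fast non-monotonic drift needs more bins.
* FRAP fitting is a phenomenological single-exponential; half-times from
  different mechanistic models are not directly comparable.
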