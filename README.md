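# nanocluster

Quantitative single-molecule localization microscopy (SMLM/dSTORM) analysis
of membrane-receptor nanoclusters at the immune synapse.

When an inhibitory or activating receptor on a T cell is engaged by its
ligand, it reorganizes from a dispersed membrane distribution into dense,
sub-micron nanoclusters that coalesce with T-cell-receptor clusters at the
immune synapse. Measuring that reorganization requires a chain of
quantitative steps that this package implements end to end:

1. **Reconstruction** — à-trous B-spline wavelet filtering (order 3,
   scale 2), local-maximum detection on the F2 plane at 2×SD(F1), and
   integrated-Gaussian Poisson maximum-likelihood fitting (fit radius 5 px,
   initial σ 1.6 px) with Mortensen-style uncertainty estimates.
2. **Post-processing** — quality filters (photons > 600, σ ∈ [50, 200] nm,
   uncertainty < 30 nm), cross-correlation drift correction (3 temporal
   bins, magnification 5), and re-blink merging (50 nm, 20 frames).
3. **Cluster statistics** — Ripley's K/L/H with
   `K̂(r) = |A|/(n(n−1)) Σ_{i≠j} 1(d_ij ≤ r)`, `L = √(K/π)`, `H = L − r`,
   and the H-peak radius; Getis–Franklin local `L_i(r)` maps thresholded
   against a CSR-simulation null into binary cluster maps, with per-region
   metrics (density, mean cluster area, in-cluster density, number of
   clusters, fraction of events in clusters).
4. **Colocalization** — coordinate-based colocalization
   (`C_a = S_a·exp(−d(a,B)/r_max)`, fraction of scores > 0.8),
   cross-channel nearest-neighbour distances (modal 10-nm bin), Voronoi
   tessellation Spearman and Mander's coefficients, and the
   reversed-coordinate negative control.
5. **Pixel metrics** — per-cell clustering index (fraction of ROI pixels
   above 1.5× the ROI mean), synaptic enrichment (log2 fold change of
   background-subtracted means), and FRAP recovery fits
   `I(t) = M(1 − 2^(−t/t½))`.
6. **Synthetic data** — CSR and Thomas (Neyman–Scott) point processes with
   exact closed-form Ripley K under toroidal wrapping, two-channel patterns
   with a tunable colocalized fraction, blinking-emitter movies with known
   ground truth and injected drift, FRAP traces, and synapse images with an
   exact bright-pixel fraction.

It is aimed at microscopists and computational biologists who need the
published processing recipe as reusable, tested functions rather than a
collection of vendor tools and one-off scripts.

## Worked example

Simulate a clustered (Thomas) pattern at the ligated-receptor scale and
quantify it:

```r
library(nanocluster)

p <- simulate_thomas(kappa = 4, mu = 25, sigma_nm = 50,
                     width_um = 5, height_um = 5, seed = 3)

curve <- ripley_k(p)                          # K, L, H over 10-500 nm
map   <- segment_clusters(getis_franklin_map(p), seed = 3)
cluster_metrics(map)
#> cluster_metrics: 91.6 /um^2 overall, 62 clusters, mean area 39281 nm^2,
#>   in-cluster density 768 /um^2, fraction in clusters 0.817
h_peak(curve)
#> [1] 170
```

Read: the region holds 91.6 localizations/µm² overall; segmentation finds
62 nanoclusters of ~3.9 × 10⁴ nm² mean area whose internal density
(768/µm²) is ~8-fold the regional average, with 82% of localizations
inside clusters; the Ripley H function peaks at 170 nm, the characteristic
cluster radius for these generator settings (σ = 50 nm scatter plus the
finite cluster population).

FRAP kinetics from a noiseless synthetic trace:

```r
fit <- fit_frap(simulate_frap_trace(t_half_s = 14.85, mobile_fraction = 0.96,
                                    noise_sd = 0, duration_s = 300))
fit
#> frap_fit: t_half = 14.85 s, mobile fraction = 0.960 (RMS 0.0000)
predict(fit, 300)   # recovery 300 s after the bleach
#> [1] 0.9599992
```

A thin CLI over the same functions is installed at
`inst/scripts/smlm-pipeline.R`, with subcommands `simulate`, `reconstruct`,
`postprocess`, `cluster`, `coloc`, `pixel-metrics` and `frap`, each taking
`--config`, `--seed`, `--out`:

```sh
Rscript inst/scripts/smlm-pipeline.R simulate --kind thomas --seed 3 --out locs
Rscript inst/scripts/smlm-pipeline.R cluster --in locs.csv \
    --region 0,0,5000,5000 --out metrics.json
```

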