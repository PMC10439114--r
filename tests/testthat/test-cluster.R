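test_that("Ripley estimator reproduces hand-computed and brute-force values", {
  # two points 100 nm apart in 1x1 um: K jumps to the full area at r >= 100
  p2 <- point_pattern(c(450, 550), c(500, 500), 1000, 1000)
  cv <- ripley_k(p2, radii_nm = c(50, 100, 200))
  expect_equal(cv$K, c(0, 1e6, 1e6))
  expect_equal(cv$L[2], sqrt(1e6 / pi))
  expect_equal(cv$H[2], sqrt(1e6 / pi) - 100, tolerance = 1e-9)
  # production counts equal the O(n^2) reference exactly
  for (s in 1:3) {
    p <- simulate_thomas(4, 25, 50, 2.5, 2.5, seed = s)
    expect_lte(npoints(p), 1000)
    rs <- seq(20, 400, by = 20)
    for (tor in c(FALSE, TRUE)) {
      cv <- ripley_k(p, rs, if (tor) "toroidal" else "none")
      expect_equal(cv$K, brute_ripley_k(p, rs, tor))
    }
  }
  expect_error(ripley_k(point_pattern(1, 1, 1000, 1000)), "fewer than 2")
  expect_error(ripley_k(p2, radii_nm = 600), "half the shorter")
})

test_that("Ripley K is invariant to translation, rotation and scaling", {
  p <- simulate_thomas(4, 25, 50, 2, 2, seed = 4)
  rs <- seq(20, 400, by = 20)
  k0 <- ripley_k(p, rs)$K
  shift <- point_pattern((p$x + 700) %% 2000, (p$y + 300) %% 2000, 2000, 2000)
  expect_equal(ripley_k(shift, rs, "toroidal")$K,
               ripley_k(point_pattern(p$x, p$y, 2000, 2000), rs,
                        "toroidal")$K)
  rot <- point_pattern(p$y, p$width_nm - p$x, p$height_nm, p$width_nm)
  expect_equal(ripley_k(rot, rs)$K, k0)
  sc <- point_pattern(2 * p$x, 2 * p$y, 2 * p$width_nm, 2 * p$height_nm)
  cs <- ripley_k(sc, 2 * rs)
  expect_equal(cs$K, 4 * k0)
  expect_equal(attr(cs, "peak_radius_nm"), 2 * attr(ripley_k(p, rs),
                                                    "peak_radius_nm"))
})

test_that("CSR H is a null and larger cluster scatter moves the H peak out", {
  hs <- vapply(1:50, function(s)
    ripley_k(simulate_csr(5, 5, 100, seed = s),
             edge_correction = "toroidal")$H, numeric(50))
  z <- rowMeans(hs) / (apply(hs, 1, sd) / sqrt(50))
  expect_lt(max(abs(z)), 2)
  peaks <- vapply(c(50, 200), function(sg) {
    median(vapply(1:25, function(s)
      attr(ripley_k(simulate_thomas(4, 25, sg, 5, 5, seed = s),
                    edge_correction = "toroidal"), "peak_radius_nm"),
      numeric(1)))
  }, numeric(1))
  expect_lt(peaks[1], peaks[2])
})

test_that("h_peak applies the tie rule and the no-clustering sentinel", {
  flat <- structure(data.frame(r_nm = 1:10, H = rep(0, 10)),
                    class = c("ripley_curve", "data.frame"))
  expect_true(is.na(h_peak(flat)))
  plateau <- structure(data.frame(r_nm = 1:10,
                                  H = c(0, 1, 3, 3, 3, 2, 1, 0, 0, 0)),
                       class = c("ripley_curve", "data.frame"))
  expect_equal(h_peak(plateau), 3)
})

test_that("Getis-Franklin local values follow the formula", {
  # point with exactly m neighbours within r: L_i = sqrt(A m / (pi (n-1)))
  p <- point_pattern(c(1000, 1020, 1040, 4000), c(1000, 1000, 1000, 4000),
                     5000, 5000)
  m <- getis_franklin_map(p, r_local_nm = 50, grid_step_nm = 50)
  A <- 5000 * 5000
  expect_equal(m$L_i,
               sqrt(A * c(2, 2, 2, 0) / (pi * 3)))
  # isolated point has L_i = 0 and its surroundings interpolate to 0
  expect_equal(m$L_i[4], 0)
  # CSR: E[L_i^2] = r^2 exactly, so the RMS of local L approaches r
  ml <- vapply(1:30, function(s) {
    pp <- simulate_csr(5, 5, 100, seed = s)
    mean(getis_franklin_map(pp, grid_step_nm = 100)$L_i^2)
  }, numeric(1))
  expect_lt(abs(sqrt(mean(ml)) / 50 - 1), 0.1)
})

test_that("CSR patterns stay below the cluster threshold", {
  fr <- vapply(1:20, function(s) {
    p <- simulate_csr(5, 5, 100, seed = s)
    m <- segment_clusters(getis_franklin_map(p, grid_step_nm = 20),
                          seed = s + 1000)
    cm <- cluster_metrics(m)
    c(cm$fraction_in_clusters, mean(m$binary))
  }, numeric(2))
  expect_lt(median(fr[1, ]), 0.05)
  expect_lt(max(fr[2, ]), 0.02)
})

test_that("a synthetic disc segments into one cluster of the expected area", {
  ratios <- vapply(1:8, function(s) {
    p <- make_disc_pattern(100, 200, seed = s)
    m <- segment_clusters(getis_franklin_map(p, grid_step_nm = 10),
                          seed = s + 600)
    cm <- cluster_metrics(m)
    expect_equal(cm$n_clusters, 1)
    expect_gt(cm$fraction_in_clusters, 0.9)
    cm$mean_cluster_area_nm2 / (pi * (200 + 50)^2)
  }, numeric(1))
  # smoothing halo: the thresholded area approximates the r_local-dilated disc
  expect_lt(abs(median(ratios) - 1), 0.25)
  # empty pattern gives an empty map
  empty <- point_pattern(numeric(), numeric(), 5000, 5000)
  m0 <- segment_clusters(getis_franklin_map(empty, grid_step_nm = 50))
  expect_equal(sum(m0$binary), 0)
  expect_equal(cluster_metrics(m0)$fraction_in_clusters, 0)
})

test_that("cluster metrics aggregate labelled components correctly", {
  p <- rbind_patterns <- point_pattern(
    c(make_disc_pattern(60, 150, cx = 1200, cy = 1200, seed = 1)$x,
      make_disc_pattern(60, 150, cx = 3800, cy = 3800, seed = 2)$x),
    c(make_disc_pattern(60, 150, cx = 1200, cy = 1200, seed = 1)$y,
      make_disc_pattern(60, 150, cx = 3800, cy = 3800, seed = 2)$y),
    5000, 5000)
  m <- segment_clusters(getis_franklin_map(p, grid_step_nm = 10), seed = 5)
  cm <- cluster_metrics(m)
  expect_equal(cm$n_clusters, 2)
  expect_equal(cm$fraction_in_clusters, 1)
  expect_equal(cm$density_per_um2, 120 / 25)
  # two equal discs: component areas agree within smoothing noise
  areas <- tabulate(m$labels[m$labels > 0]) * 100
  expect_lt(abs(diff(areas)) / mean(areas), 0.25)
  # recovered area grows with generator scatter (bright, well-populated
  # nanoclusters so that even diffuse ones stay above the CSR threshold)
  med_area <- vapply(c(25, 50, 100), function(sg) {
    median(vapply(1:10, function(s) {
      pp <- simulate_thomas(1, 150, sg, 5, 5, seed = s)
      mm <- segment_clusters(getis_franklin_map(pp, grid_step_nm = 20),
                             seed = s + 40)
      cluster_metrics(mm)$mean_cluster_area_nm2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_area) > 0))
})
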