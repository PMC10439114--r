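test_that("CSR generator matches Poisson expectations and is reproducible", {
  counts <- vapply(1:200, function(s)
    npoints(simulate_csr(5, 5, 100, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 2500), 3 * sqrt(2500))
  p1 <- simulate_csr(2, 2, 50, seed = 42)
  p2 <- simulate_csr(2, 2, 50, seed = 42)
  expect_identical(p1, p2)
  expect_error(simulate_csr(0, 2, 50), "zero-area")
  # a realistic unligated-receptor density
  n22 <- mean(vapply(1:50, function(s)
    npoints(simulate_csr(5, 5, 22, seed = s)), numeric(1)))
  expect_lt(abs(n22 - 550), 3 * sqrt(550))
})

test_that("Thomas generator has the right intensity and degenerate limit", {
  counts <- vapply(1:100, function(s)
    npoints(simulate_thomas(4, 25, 50, 5, 5, seed = s)), numeric(1))
  # var of Thomas count = kappa*area*(mu + mu^2)
  expect_lt(abs(mean(counts) - 2500), 3 * sqrt(100 * (25 + 625)) / 10)
  p <- simulate_thomas(4, 25, 0, 5, 5, seed = 3)
  parents <- attr(p, "parents")
  ids <- attr(p, "parent_id")
  expect_equal(p$x, parents$x[ids] %% 5000)
  expect_equal(p$y, parents$y[ids] %% 5000)
})

test_that("empirical Thomas K matches the closed form", {
  rs <- seq(50, 500, by = 50)
  ks <- vapply(1:50, function(s)
    ripley_k(simulate_thomas(4, 25, 50, 5, 5, seed = s), rs,
             "toroidal")$K, numeric(length(rs)))
  ratio <- rowMeans(ks) / thomas_k_theoretical(rs, 4, 50)
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("two-channel generator controls the shared-centre fraction", {
  tc <- simulate_two_channel(coloc_fraction = 1, offset_nm = 0, seed = 2)
  expect_equal(nrow(tc$pairing),
               nrow(attr(tc$A, "parents")))
  expect_equal(tc$pairing$ax, tc$pairing$bx)
  tc0 <- simulate_two_channel(coloc_fraction = 0, seed = 2)
  expect_equal(nrow(tc0$pairing), 0)
  # half of B's parents near an A parent at fraction 0.5
  tc5 <- simulate_two_channel(coloc_fraction = 0.5, offset_nm = 20, seed = 7)
  shared <- nrow(tc5$pairing)
  total <- nrow(attr(tc5$A, "parents"))
  expect_gt(shared / total, 0.3)
  expect_lt(shared / total, 0.7)
  d <- sqrt((tc5$pairing$ax - tc5$pairing$bx)^2 +
            (tc5$pairing$ay - tc5$pairing$by)^2)
  # Rayleigh displacement: 3-sigma radius covers ~98.9 % of shared parents
  expect_gt(mean(d <= 3 * 20), 0.9)
})

test_that("blink movies conserve photons and honour ground truth", {
  on <- matrix(TRUE, 1, 1)
  mv <- simulate_blink_movie(1600, 1600, on, photons = 5000,
                             field_px = c(32, 32), background_photons = 0,
                             poisson_noise = FALSE, seed = 1)
  expect_lt(abs(sum(mv$frames) - 5000) / 5000, 0.001)
  # zero emitters -> pure Poisson background
  mv0 <- simulate_blink_movie(numeric(), numeric(),
                              matrix(FALSE, 3, 0), field_px = c(16, 16),
                              background_photons = 7, seed = 2)
  expect_lt(abs(mean(mv0$frames) - 7), 3 * sqrt(7 / length(mv0$frames)))
  # photon bookkeeping with signal, background and noise
  set.seed(3)
  on2 <- matrix(runif(10 * 4) < 0.5, 10, 4)
  mv2 <- simulate_blink_movie(c(800, 1600, 2400, 900),
                              c(800, 900, 1500, 2300), on2,
                              photons = 1500, field_px = c(32, 32),
                              background_photons = 5, seed = 3)
  expected <- sum(on2) * 1500 + 5 * 32 * 32 * 10
  expect_lt(abs(sum(mv2$frames) - expected), 3 * sqrt(expected))
  # emitter outside the field warns and is skipped
  expect_warning(
    mv3 <- simulate_blink_movie(c(1600, 99000), c(1600, 1600),
                                matrix(TRUE, 1, 2), photons = 1000,
                                field_px = c(32, 32),
                                poisson_noise = FALSE, seed = 1),
    "outside field")
  expect_lt(sum(mv3$frames), 1001)
})

test_that("FRAP traces follow the closed-form recovery", {
  tr <- simulate_frap_trace(14.85, 0.96, noise_sd = 0, duration_s = 300,
                            dt_s = 0.05)
  post <- tr$time_s >= tr$bleach_time_s
  t <- tr$time_s[post] - tr$bleach_time_s
  expect_equal(tr$intensity[post], 0.96 * (1 - 2^(-t / 14.85)))
  # half of the mobile pool recovered at t = t_half
  at_half <- which(abs(t - 14.85) == min(abs(t - 14.85)))[1]
  expect_equal(tr$intensity[post][at_half], 0.48, tolerance = 1e-2)
  # plateau approaches the mobile fraction
  expect_equal(tail(tr$intensity, 1), 0.96, tolerance = 1e-6)
  expect_true(all(tr$intensity[!post] == 1))
  expect_true(all(diff(tr$time_s) > 0))
})

test_that("synapse images carry exact bright-fraction ground truth", {
  img0 <- simulate_synapse_image(c(40, 40), bright_fraction = 0, seed = 1)
  expect_equal(sd(img0$values), 0)
  img <- simulate_synapse_image(c(40, 40), bright_fraction = 0.1,
                                contrast = 10, seed = 2)
  expect_length(attr(img, "bright_index"), 160)
  # masked-out pixels never bright
  mask <- matrix(FALSE, 40, 40); mask[11:30, 11:30] <- TRUE
  img2 <- simulate_synapse_image(c(40, 40), cell_mask = mask,
                                 bright_fraction = 0.2, seed = 3)
  expect_true(all(img2$values[!mask] == 100))
  expect_equal(sum(img2$values[mask] > 100), round(0.2 * sum(mask)))
})
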