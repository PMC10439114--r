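test_that("quality filter applies the published strict/closed bounds", {
  tb <- localization_table(frame = 1:4,
                           x_nm = rep(100, 4), y_nm = rep(100, 4),
                           photons = c(700, 600, 700, 700),
                           sigma_nm = c(100, 100, 210, 100),
                           uncertainty_nm = c(10, 10, 10, 30))
  out <- filter_localizations(tb)
  expect_equal(nrow(out), 1)
  expect_equal(out$photons, 700)
  expect_equal(out$sigma_nm, 100)
  expect_equal(out$uncertainty_nm, 10)
  # boundary values: sigma bounds closed, photon/uncertainty bounds strict
  edge <- localization_table(frame = 1:2, x_nm = 1, y_nm = 1,
                             photons = c(601, 601), sigma_nm = c(50, 200),
                             uncertainty_nm = c(29.999, 29.999))
  expect_equal(nrow(filter_localizations(edge)), 2)
  # wide-open criteria are the identity
  expect_equal(nrow(filter_localizations(tb, 0, c(0, Inf), Inf)), 4)
  expect_equal(nrow(filter_localizations(localization_table())), 0)
})

test_that("drift estimation recovers injected linear drift", {
  make_drifted <- function(seed, v_x = 0.5, v_y = 0.2, n_loc = 2000,
                           n_frames = 3000) {
    set.seed(seed)
    base <- simulate_thomas(4, 25, 50, 5, 5, seed = seed)
    idx <- sample(npoints(base), n_loc, replace = TRUE)
    fr <- sort(sample(n_frames, n_loc, replace = TRUE))
    localization_table(frame = fr, x_nm = base$x[idx] + v_x * fr,
                       y_nm = base$y[idx] + v_y * fr, sigma_nm = 150,
                       photons = 1000, uncertainty_nm = 10)
  }
  tb <- make_drifted(1)
  dt <- estimate_drift(tb)
  expect_equal(dt$frame, min(tb$frame):max(tb$frame))
  # zero at the first bin midpoint, by construction relative to bin 1
  expect_equal(dt$dx_nm[1], dt$dx_nm[2], tolerance = 1)
  # recovered offset between the outer bin midpoints (0.5 nm/frame x 2000)
  expect_lt(abs(dt$dx_nm[nrow(dt)] - 0.5 * 2000), 10)
  expect_lt(abs(dt$dy_nm[nrow(dt)] - 0.2 * 2000), 10)
  # null case: no injected drift stays within a histogram bin
  tb0 <- make_drifted(2, v_x = 0, v_y = 0)
  dt0 <- estimate_drift(tb0)
  expect_lt(max(abs(c(dt0$dx_nm, dt0$dy_nm))), 20)
  # closed loop: residual frame-to-frame drift of the corrected track is
  # below 5 nm (extrapolated end segments keep the raw 0.5 nm/frame)
  resid_track <- 0.5 * dt$frame - dt$dx_nm
  expect_lt(max(abs(diff(resid_track))), 5)
  sparse <- tb[seq(1, nrow(tb), by = 100), ]
  expect_error(suppressWarnings(estimate_drift(sparse)), "fewer than 10")
})

test_that("apply_drift shifts coordinates and checks coverage", {
  tb <- localization_table(frame = c(1, 2), x_nm = c(100, 100),
                           y_nm = c(50, 50), sigma_nm = 150,
                           photons = 1000, uncertainty_nm = 10)
  zero <- structure(data.frame(frame = 1:2, dx_nm = 0, dy_nm = 0),
                    class = c("drift_track", "data.frame"))
  expect_equal(apply_drift(tb, zero)$x_nm, tb$x_nm)
  const <- transform(zero, dx_nm = 10)
  expect_equal(apply_drift(tb, const)$x_nm, tb$x_nm - 10)
  short <- zero[1, ]
  expect_error(apply_drift(tb, short), "cover")
})

test_that("re-blink merging follows the gap/distance rules", {
  tb <- localization_table(frame = c(1, 5, 40), x_nm = rep(1000, 3),
                           y_nm = rep(1000, 3), sigma_nm = 150,
                           photons = c(700, 800, 900), uncertainty_nm = 10)
  m <- merge_reblinks(tb)
  expect_equal(nrow(m), 2)
  expect_equal(m$n_merged, c(2L, 1L))
  expect_equal(m$frame, c(1L, 40L))
  # photon-weighted centroid and summed photons
  expect_equal(m$photons, c(1500, 900))
  # two simultaneous events 200 nm apart never merge
  tb2 <- localization_table(frame = rep(1:10, 2),
                            x_nm = c(rep(1000, 10), rep(1200, 10)),
                            y_nm = rep(1000, 20), sigma_nm = 150,
                            photons = 1000, uncertainty_nm = 10)
  expect_equal(nrow(merge_reblinks(tb2)), 2)
  # combined uncertainty is the inverse-variance combination
  tb3 <- localization_table(frame = 1:2, x_nm = c(1000, 1010),
                            y_nm = 1000, sigma_nm = 150, photons = 1000,
                            uncertainty_nm = c(10, 20))
  m3 <- merge_reblinks(tb3)
  expect_equal(m3$uncertainty_nm, 1 / sqrt(1 / 100 + 1 / 400))
})

test_that("merging conserves photons, is idempotent and recovers molecules", {
  set.seed(2)
  nmol <- 40
  x <- runif(nmol, 500, 4500); y <- runif(nmol, 500, 4500)
  rows <- lapply(seq_len(nmol), function(i) {
    f <- sample(1:60, 1); evs <- c()
    for (b in seq_len(sample(1:3, 1))) {
      len <- sample(2:4, 1)
      evs <- c(evs, f:(f + len - 1))
      f <- f + len + sample(3:15, 1)
    }
    localization_table(frame = evs,
                       x_nm = x[i] + rnorm(length(evs), 0, 8),
                       y_nm = y[i] + rnorm(length(evs), 0, 8),
                       sigma_nm = 150, photons = 1000, uncertainty_nm = 10)
  })
  tb <- do.call(rbind, rows)
  m <- merge_reblinks(tb)
  expect_equal(nrow(m), nmol)
  expect_equal(sum(m$photons), sum(tb$photons))
  expect_equal(nrow(merge_reblinks(m)), nrow(m))
  # anchor switch accepted
  expect_equal(nrow(merge_reblinks(tb, anchor = "first")), nmol)
})
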