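# shared fixtures and independent oracles

# uniform disc of points, centre (cx, cy), radius r, inside a square region
make_disc_pattern <- function(n, r_nm = 200, cx = 2500, cy = 2500,
                              side_nm = 5000, seed = 1) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  rr <- r_nm * sqrt(runif(n))
  point_pattern(cx + rr * cos(th), cy + rr * sin(th), side_nm, side_nm)
}

# O(n^2) direct-count Ripley K reference
brute_ripley_k <- function(p, radii, toroidal = FALSE) {
  n <- npoints(p)
  dx <- abs(outer(p$x, p$x, "-")); dy <- abs(outer(p$y, p$y, "-"))
  if (toroidal) {
    dx <- pmin(dx, p$width_nm - dx)
    dy <- pmin(dy, p$height_nm - dy)
  }
  d <- sqrt(dx^2 + dy^2)
  diag(d) <- Inf
  area <- p$width_nm * p$height_nm
  vapply(radii, function(r) area / (n * (n - 1)) * sum(d <= r), numeric(1))
}

# O(n*m) brute-force cross nearest-neighbour distances
brute_nnd <- function(A, B) {
  d <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2)
  apply(d, 1, min)
}

# emitters on a jittered grid, clear of the fitting margin; returns truth and
# the rendered movie
make_blink_benchmark <- function(n_emitters = 50, n_frames = 25,
                                 on_per_emitter = 5, photons = 2000,
                                 background = 10, field_px = 90, seed = 5) {
  set.seed(seed)
  g <- expand.grid(gx = 1:8, gy = 1:7)[seq_len(n_emitters), ]
  x <- 700 + (g$gx - 1) * 1050 + runif(n_emitters, 0, 40)
  y <- 700 + (g$gy - 1) * 1250 + runif(n_emitters, 0, 40)
  on <- matrix(FALSE, n_frames, n_emitters)
  for (e in seq_len(n_emitters)) on[sample(n_frames, on_per_emitter), e] <- TRUE
  movie <- simulate_blink_movie(x, y, on, photons = photons,
                                field_px = c(field_px, field_px),
                                background_photons = background,
                                psf_sigma_nm = 160, seed = seed + 1)
  list(x = x, y = y, on = on, movie = movie)
}

# recall and RMSE of a reconstruction against per-frame emitter truth
match_reconstruction <- function(table, x, y, on, tol_nm = 150) {
  hits <- 0; errs <- c()
  for (f in seq_len(nrow(on))) {
    rows <- table[table$frame == f, , drop = FALSE]
    for (e in which(on[f, ])) {
      if (!nrow(rows)) next
      d <- sqrt((rows$x_nm - x[e])^2 + (rows$y_nm - y[e])^2)
      if (min(d) < tol_nm) {
        hits <- hits + 1
        errs <- c(errs, min(d))
      }
    }
  }
  list(recall = hits / sum(on), rmse = sqrt(mean(errs^2)))
}

# one-sided permutation trend test: does `values[seed, level]` increase
# (direction = 1) or decrease (-1) with the level index?
perm_trend_p <- function(values, direction = 1, n_perm = 999, seed = 1) {
  set.seed(seed)
  lv <- col(values)
  stat <- function(v) suppressWarnings(
    cor(as.vector(lv), as.vector(v), method = "spearman"))
  obs <- direction * stat(values)
  perm <- replicate(n_perm, {
    shuffled <- t(apply(values, 1, sample))
    direction * stat(shuffled)
  })
  (1 + sum(perm >= obs)) / (n_perm + 1)
}
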