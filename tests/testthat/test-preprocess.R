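make_cube <- function(arr, B = NULL) {
  B <- if (is.null(B)) dim(arr)[3] else B
  hypercube(arr, make_band_axis("NIR", B, 874, 1734))
}

test_that("flat-field calibration is exact on reference inputs", {
  d <- c(4, 5, 6)
  dark <- make_cube(array(0.1, d))
  white <- make_cube(array(0.9, d))
  raw_w <- make_cube(array(0.9, d))
  raw_d <- make_cube(array(0.1, d))
  raw_m <- make_cube(array(0.5, d))
  expect_equal(calibrate_reflectance(raw_w, dark, white)$values, array(1, d))
  expect_equal(calibrate_reflectance(raw_d, dark, white)$values, array(0, d))
  expect_equal(calibrate_reflectance(raw_m, dark, white)$values, array(0.5, d))
})

test_that("degenerate calibration names the first offending voxel", {
  d <- c(3, 3, 4)
  dark <- make_cube(array(0.1, d))
  wv <- array(0.9, d); wv[2, 3, 1] <- 0.1
  expect_error(calibrate_reflectance(make_cube(array(0.5, d)), dark,
                                     make_cube(wv)),
               "\\(2, 3\\), band 1")
})

test_that("calibration commutes with band trimming", {
  set.seed(8)
  d <- c(3, 4, 12)
  ax <- make_band_axis("NIR", 12, 874, 1734)
  raw <- hypercube(array(runif(prod(d), 0.2, 0.8), d), ax)
  dark <- hypercube(array(runif(prod(d), 0, 0.1), d), ax)
  white <- hypercube(array(runif(prod(d), 0.9, 1), d), ax)
  iv <- c(1000, 1500)
  keep <- which(ax$values >= iv[1] & ax$values <= iv[2])
  cal <- calibrate_reflectance(raw, dark, white)
  trim_then_cal <- calibrate_reflectance(
    hypercube(raw$values[, , keep], band_axis("NIR", ax$values[keep])),
    hypercube(dark$values[, , keep], band_axis("NIR", ax$values[keep])),
    hypercube(white$values[, , keep], band_axis("NIR", ax$values[keep])))
  expect_equal(cal$values[, , keep], trim_then_cal$values)
})

test_that("segmentation recovers noiseless planted footprints exactly", {
  s <- planted_band_set(seed = 3L, n_per_cell = 3L, B = 30L, noise = 0.01)
  # give the reference band a strong signal by using an NIR-like axis value
  sim <- simulate_hypercube(4L, c(60, 60), s, rng_seed = 7)
  cube <- hypercube(sim$cube$values,
                    make_band_axis("NIR", 30, 874, 1734))
  cfg <- preprocess_config(ref_band_value = 1363, min_component_px = 5L)
  mask <- segment_seeds(cube, cfg)
  expect_equal(mask$n_seeds, 4L)
  # identical pixel sets up to label permutation in raster order
  for (k in 1:4) {
    truth <- sim$labels == k
    lab <- unique(mask$labels[truth])
    expect_length(lab, 1L)
    expect_true(all((mask$labels == lab) == truth))
  }
})

test_that("constant images segment to zero seeds", {
  cube <- make_cube(array(0.5, c(20, 20, 5)), 5)
  expect_equal(segment_seeds(cube, preprocess_config())$n_seeds, 0L)
  expect_error(segment_seeds(cube, preprocess_config(ref_band_value = 10)),
               "outside")
})

test_that("connected-component labels agree with a union-find oracle", {
  set.seed(11)
  mask <- matrix(runif(30 * 30) < 0.3, 30, 30)
  labels <- seedcascade:::label_components(mask, 8L)
  # independent union-find over all pixel pairs
  parent <- seq_len(900)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  idx <- function(r, c) (c - 1L) * 30L + r
  for (r in 1:30) for (c in 1:30) {
    if (!mask[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if ((dr | dc) && rr >= 1 && rr <= 30 && cc >= 1 && cc <= 30 &&
          mask[rr, cc]) {
        a <- find(idx(r, c)); b <- find(idx(rr, cc))
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(which(mask), find, integer(1))
  oracle_comp <- match(roots, unique(roots))
  got_comp <- labels[mask]
  expect_equal(length(unique(got_comp)), length(unique(oracle_comp)))
  # same partition: the component ids are a relabeling of each other
  expect_equal(length(unique(paste(got_comp, oracle_comp))),
               length(unique(oracle_comp)))
})

test_that("mean spectra equal the brute-force per-band average", {
  set.seed(12)
  arr <- array(runif(10 * 10 * 6), c(10, 10, 6))
  cube <- make_cube(arr, 6)
  labels <- matrix(0L, 10, 10)
  labels[2, 2] <- 1L                       # single pixel
  labels[5, 5:7] <- 2L; labels[6, 5:6] <- 2L  # 5-pixel seed
  mask <- structure(list(labels = labels, n_seeds = 2L), class = "seed_mask")
  out <- extract_mean_spectra(cube, mask)
  expect_equal(out$spectra[1, ], arr[2, 2, ], ignore_attr = TRUE)
  px <- which(labels == 2L, arr.ind = TRUE)
  brute <- rep(0, 6)
  for (i in seq_len(nrow(px))) brute <- brute + arr[px[i, 1], px[i, 2], ]
  expect_equal(out$spectra[2, ], brute / nrow(px), ignore_attr = TRUE)
  # empty mask
  empty <- structure(list(labels = matrix(0L, 10, 10), n_seeds = 0L),
                     class = "seed_mask")
  expect_equal(n_samples(extract_mean_spectra(cube, empty)), 0L)
})

test_that("moving average matches the truncated-window reference", {
  ax <- make_band_axis("NIR", 9, 874, 1734)
  set.seed(3)
  y <- runif(9)
  s <- spectrum_set(matrix(y, 1), ax)
  expect_equal(moving_average(s, 1L)$spectra[1, ], y, ignore_attr = TRUE)
  sc <- spectrum_set(matrix(0.7, 1, 9), ax)
  expect_equal(moving_average(sc, 5L)$spectra[1, ], rep(0.7, 9),
               ignore_attr = TRUE)
  # brute-force shrinking-window loop
  ref <- vapply(1:9, function(j) mean(y[max(1, j - 2):min(9, j + 2)]),
                numeric(1))
  expect_equal(moving_average(s, 5L)$spectra[1, ], ref, ignore_attr = TRUE)
  expect_error(moving_average(s, 4L), "odd")
  # never extends the value range
  for (w in c(3L, 5L, 7L)) {
    sm <- moving_average(s, w)$spectra[1, ]
    expect_gte(min(sm), min(y))
    expect_lte(max(sm), max(y))
  }
})

test_that("airPLS recovers smooth baselines under peaks", {
  expect_equal(airpls_baseline(rep(0, 50))$corrected, rep(0, 50))
  # pure smooth quadratic: corrected residual < 1% of input range
  u <- seq(-1, 1, length.out = 80)
  quad <- 2 + 0.5 * u + 0.8 * u^2
  r <- airpls_baseline(quad, lambda = 1, iters = 15)
  expect_lt(max(abs(r$corrected)), 0.01 * diff(range(quad)))
  # Gaussian peaks on a linear drift: apexes preserved, baseline RMSE small
  # (broad peaks need a correspondingly stiff penalty)
  x <- seq_len(120)
  drift <- 0.5 + 0.004 * x            # amplitude ~0.48 over the window
  peaks <- 0.9 * exp(-0.5 * ((x - 30) / 4)^2) +
    0.7 * exp(-0.5 * ((x - 85) / 5)^2)
  r2 <- airpls_baseline(drift + peaks, lambda = 1e4, iters = 15)
  expect_equal(which.max(r2$corrected[15:45]) + 14L, 30L)
  expect_equal(which.max(r2$corrected[70:100]) + 69L, 85L)
  drift_amp <- diff(range(drift))
  expect_lt(sqrt(mean((r2$baseline - drift)^2)), 0.05 * drift_amp)
  expect_error(airpls_baseline(c(1, NA, 3)), "finite")
})

test_that("airPLS negative-residual mass shrinks across iterations", {
  x <- seq_len(100)
  y <- 0.3 + 0.003 * x + exp(-0.5 * ((x - 40) / 5)^2)
  mass <- vapply(1:8, function(it) {
    r <- airpls_baseline(y, lambda = 10, iters = it)
    sum(pmax(-r$corrected, 0))
  }, numeric(1))
  expect_true(all(diff(mass) <= 1e-9))
})

test_that("band trimming keeps the closed interval and the printed count", {
  s256 <- spectrum_set(matrix(0.5, 2, 256), nir_band_axis())
  trimmed <- trim_bands(s256, c(958, 1630))
  expect_equal(length(trimmed$band_axis), 200L)
  expect_true(all(trimmed$band_axis$values >= 958 &
                    trimmed$band_axis$values <= 1630))
  # identity on a covering interval
  full <- trim_bands(s256, c(800, 1800))
  expect_equal(full$band_axis$values, s256$band_axis$values)
  # 10-band toy: brute-force membership
  ax <- make_band_axis("THz", 10, 0.3, 2.0)
  s10 <- spectrum_set(matrix(runif(30), 3), ax)
  iv <- c(0.6, 1.4)
  keep <- which(ax$values >= iv[1] & ax$values <= iv[2])
  expect_equal(trim_bands(s10, iv)$band_axis$values, ax$values[keep])
  expect_error(trim_bands(s10, c(5, 6)), "interval")
})
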