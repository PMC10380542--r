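test_that("zero-noise, zero-offset simulation reproduces the templates exactly", {
  ax <- tiny_axis(10)
  tmpl <- rbind(a = seq(0.2, 0.4, length.out = 10),
                b = seq(0.5, 0.9, length.out = 10))
  d <- sim_design(ax, c("a", "b"), tmpl, gm_offset = 0,
                  discriminative_bands = integer(0), noise_sd = 0,
                  drift_sd = 0, class_sizes = matrix(3L, 2, 2), rng_seed = 9)
  s <- simulate_spectrum_set(d)
  expect_equal(n_samples(s), 12L)
  for (i in seq_len(12)) {
    expect_equal(s$spectra[i, ], tmpl[s$variety[i], ], ignore_attr = TRUE)
  }
})

test_that("the default terahertz design carries the acquisition class sizes", {
  d <- sim_design_thz()
  expect_equal(as.integer(t(d$class_sizes)),
               c(550L, 554L, 588L, 543L, 578L, 565L))
  expect_equal(sum(d$class_sizes), 3378L)
  expect_equal(length(d$band_axis), 93L)
  # sign convention: non-GM mean >= GM mean at every band
  expect_true(all(d$gm_offset <= 0))
})

test_that("simulation is bit-identical under one seed and differs across seeds", {
  d1 <- sim_design_thz(n_per_cell = 5L, rng_seed = 21L)
  d2 <- sim_design_thz(n_per_cell = 5L, rng_seed = 21L)
  d3 <- sim_design_thz(n_per_cell = 5L, rng_seed = 22L)
  expect_identical(simulate_spectrum_set(d1)$spectra,
                   simulate_spectrum_set(d2)$spectra)
  expect_false(identical(simulate_spectrum_set(d1)$spectra,
                         simulate_spectrum_set(d3)$spectra))
})

test_that("per-band t statistics peak exactly on the offset-carrying bands", {
  # offset nonzero only at the planted indices; brute-force Welch statistic
  planted <- c(4L, 11L, 17L)
  ax <- tiny_axis(20)
  tmpl <- matrix(0.5, 1, 20)
  off <- numeric(20); off[planted] <- -0.3
  d <- sim_design(ax, "v", tmpl, off, planted, noise_sd = 0.05,
                  drift_sd = 0, class_sizes = matrix(80L, 1, 2), rng_seed = 4)
  s <- simulate_spectrum_set(d)
  tstat <- vapply(seq_len(20), function(j) {
    unname(t.test(s$spectra[s$gm == "GM", j],
                  s$spectra[s$gm == "non-GM", j])$statistic)
  }, numeric(1))
  expect_setequal(order(abs(tstat), decreasing = TRUE)[1:3], planted)
})

test_that("between-variety spacing exceeds within-variety GM spacing", {
  d <- sim_design_thz(n_per_cell = 40L, rng_seed = 31L)
  s <- simulate_spectrum_set(d)
  cell_mean <- function(v, g) {
    colMeans(s$spectra[s$variety == v & s$gm == g, , drop = FALSE])
  }
  vars <- d$varieties
  gm_d <- vapply(vars, function(v) {
    sqrt(mean((cell_mean(v, "GM") - cell_mean(v, "non-GM"))^2))
  }, numeric(1))
  between <- utils::combn(vars, 2, function(p) {
    sqrt(mean((colMeans(s$spectra[s$variety == p[1], ]) -
                 colMeans(s$spectra[s$variety == p[2], ]))^2))
  })
  expect_gt(mean(between), mean(gm_d))
  # and the noiseless design-level means obey the non-GM >= GM convention
  d0 <- sim_design_thz(n_per_cell = 3L, noise_sd = 0, drift_sd = 0)
  s0 <- simulate_spectrum_set(d0)
  for (v in vars) {
    expect_true(all(cellm <- colMeans(s0$spectra[s0$variety == v & s0$gm == "non-GM", ]) -
                      colMeans(s0$spectra[s0$variety == v & s0$gm == "GM", ]) >= -1e-12))
  }
})

test_that("hypercube simulation places disjoint connected footprints", {
  s <- planted_band_set(seed = 2L, n_per_cell = 3L)
  # empty scene
  e <- simulate_hypercube(0L, c(30, 30), s, rng_seed = 1)
  expect_true(all(e$labels == 0L))
  expect_true(all(e$cube$values == 0))
  # noiseless identity: footprint means equal the assigned spectra
  h <- simulate_hypercube(3L, c(40, 40), s, rng_seed = 2)
  for (k in 1:3) {
    px <- which(h$labels == k, arr.ind = TRUE)
    got <- colMeans(t(vapply(seq_len(nrow(px)), function(i) {
      h$cube$values[px[i, 1], px[i, 2], ]
    }, numeric(dim(h$cube)[3]))))
    expect_equal(got, unname(s$spectra[h$assignment$sample_row[k], ]))
  }
  # protocol-scale scene: 40 disjoint nonempty footprints (pixel scan)
  big <- simulate_hypercube(40L, c(200, 200), s, rng_seed = 3)
  expect_equal(sort(unique(as.integer(big$labels))), 0:40)
  sizes <- tabulate(big$labels[big$labels > 0], nbins = 40)
  expect_true(all(sizes > 0))
  # each footprint is 8-connected: a flood fill from one pixel covers it
  for (k in c(1L, 17L, 40L)) {
    px <- which(big$labels == k, arr.ind = TRUE)
    seen <- rep(FALSE, nrow(px))
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- which(!seen & abs(px[, 1] - px[f, 1]) <= 1 &
                      abs(px[, 2] - px[f, 2]) <= 1)
        seen[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
    expect_true(all(seen))
  }
})

test_that("impossible placements raise a placement failure", {
  s <- planted_band_set(seed = 2L, n_per_cell = 2L)
  expect_error(simulate_hypercube(50L, c(20, 20), s, rng_seed = 1,
                                  max_tries = 10L),
               "overlap|too small")
})
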