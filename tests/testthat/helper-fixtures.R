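# Shared fixtures, all generated in code. Trained models are memoized for
# the duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_axis <- function(B = 24L) make_band_axis("THz", B, 0.3, 2.0)

# Two well-separated spectral classes (variety-style fixture).
separable_set <- function(n_per_class = 40L, B = 24L, noise = 0.05,
                          seed = 1L) {
  ax <- tiny_axis(B)
  with_seed <- function(s, code) { # local, independent of package internals
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); force(code)
  }
  with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * B, sd = noise), 2 * n_per_class, B)
    x[(n_per_class + 1):(2 * n_per_class), 8:12] <-
      x[(n_per_class + 1):(2 * n_per_class), 8:12] + 0.8
    spectrum_set(x, ax, variety = rep(c("alpha", "beta"), each = n_per_class))
  })
}

# Binary GM-style fixture whose classes differ only at planted bands with
# graded effect sizes, each too weak to separate the classes alone: both
# selection routes must pool several bands, as in real spectra.
planted_band_design <- function(seed = 1L, B = 24L,
                                planted = c(4L, 10L, 16L, 22L),
                                effects = -c(0.24, 0.22, 0.20, 0.18),
                                n_per_cell = 150L, noise = 0.12) {
  ax <- make_band_axis("THz", B, 0.3, 2.0)
  template <- 0.3 + 0.1 * seq(0, 1, length.out = B)
  offset <- numeric(B)
  offset[planted] <- effects
  sim_design(ax, "fixture", matrix(template, 1), offset, planted,
             noise_sd = noise, drift_sd = 0,
             class_sizes = matrix(c(n_per_cell, n_per_cell), 1),
             rng_seed = seed)
}

planted_band_set <- function(seed = 1L, ...) {
  simulate_spectrum_set(planted_band_design(seed = seed, ...))
}

# Trained binary model on the planted-band fixture (memoized per seed).
planted_fixture_model <- function(seed = 1L, epochs = 40L) {
  memo(paste0("planted_model_", seed), {
    set <- planted_band_set(seed = seed)
    m <- build_cascadeseed(model_spec(length(set$band_axis), 2L),
                           rng_seed = seed)
    m <- train_model(m, set, train_config(epochs = epochs, batch_size = 64L,
                                          rng_seed = seed),
                     label = "gm")
    m$band_axis <- set$band_axis
    m
  })
}

# Trained 2-variety model on the separable fixture (memoized).
separable_fixture_model <- function(seed = 5L, epochs = 40L) {
  memo(paste0("separable_model_", seed), {
    set <- separable_set(seed = 1L)
    m <- build_cascadeseed(model_spec(length(set$band_axis), 2L),
                           rng_seed = 3L)
    m <- train_model(m, set, train_config(epochs = epochs, rng_seed = seed))
    m$band_axis <- set$band_axis
    m
  })
}
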