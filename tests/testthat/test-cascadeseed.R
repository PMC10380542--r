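test_that("the 200-band architecture reproduces the tabulated tensor shapes", {
  spec <- model_spec(200L, 3L)
  sh <- cascadeseed_shapes(spec, batch = 256L)
  # module-1 parallel convs: 1 channel in, 128 out, length preserved
  m1 <- sh[grepl("module1_conv", sh$layer), ]
  expect_equal(nrow(m1), 4L)
  expect_true(all(m1$in_channels == 1L & m1$out_channels == 128L &
                    m1$length == 200L))
  # concatenation yields the 129-channel module-2 input at full length
  m2 <- sh[grepl("module2_conv", sh$layer), ]
  expect_true(all(m2$in_channels == 129L & m2$out_channels == 64L &
                    m2$length == 200L))
  expect_true(all(sh$batch == 256L))
  # common convs preserve length; pooling halves it as floor((L-1)/2)+1
  expect_equal(sh$length[sh$layer == "common_conv1"], 200L)
  expect_equal(sh$length[sh$layer == "pool1"], 100L)
  expect_equal(sh$length[sh$layer == "pool2"], 50L)
  expect_equal(spec$flat_dim, 32L * 50L)
})

test_that("pooling arithmetic gives the 93-band head its 768 inputs", {
  spec <- model_spec(93L, 2L)
  expect_equal(spec$pooled_len, c(47L, 24L))
  expect_equal(spec$flat_dim, 768L)
  expect_error(model_spec(4L, 2L), "n_bands")
})

test_that("forward tensors match the closed-form conv/pool lengths", {
  for (B in c(9L, 24L, 93L)) {
    spec <- model_spec(B, 2L)
    m <- build_cascadeseed(spec, rng_seed = 1)
    fw <- seedcascade:::cascadeseed_forward(m$params, spec,
                                            matrix(runif(2 * B), 2),
                                            cache = TRUE)
    expect_equal(dim(fw$C1), c(spec$m1_filters + 1L, 2L * B))
    expect_equal(dim(fw$A2), c(64L, 2L * B))
    expect_equal(ncol(fw$pl1$out), 2L * spec$pooled_len[1])
    expect_equal(ncol(fw$pl2$out), 2L * spec$pooled_len[2])
    expect_equal(dim(fw$logits), c(2L, 2L))
  }
})

test_that("softmax matches the closed forms and the naive formula", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(0, log(3))), c(0.25, 0.75))
  set.seed(20)
  for (i in 1:50) {
    z <- rnorm(5, sd = 3)
    naive <- exp(z) / sum(exp(z))
    expect_equal(softmax(z), naive, tolerance = 1e-12)
    expect_equal(sum(softmax(z)), 1, tolerance = 1e-9)
    # invariance under adding a constant
    expect_equal(softmax(z + 7.3), softmax(z), tolerance = 1e-9)
  }
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("training separates a linearly separable fixture and checkpoints", {
  m <- separable_fixture_model()
  s <- separable_set(seed = 1L)
  expect_equal(m$val_accuracy, 1)
  expect_equal(mean(predict(m, s) == s$variety), 1, tolerance = 0.05)
  # checkpoint rule: returned model's validation accuracy is the history
  # max, and among max-accuracy epochs the kept one minimizes val loss
  expect_equal(m$val_accuracy, max(m$history$val_accuracy))
  at_max <- m$history[m$history$val_accuracy == m$val_accuracy, ]
  expect_equal(m$best_epoch,
               at_max$epoch[which.min(at_max$val_loss)])
  # smoothed loss decreases over the first 10 epochs
  sm <- stats::filter(m$history$loss[1:10], rep(1 / 3, 3), sides = 1)
  expect_lt(sm[10], sm[3])
})

test_that("training is deterministic and rejects degenerate inputs", {
  s <- separable_set(n_per_class = 15L, seed = 2L)
  run <- function() {
    m <- build_cascadeseed(model_spec(24L, 2L), rng_seed = 11L)
    train_model(m, s, train_config(epochs = 4L, rng_seed = 13L))
  }
  a <- run(); b <- run()
  expect_identical(a$val_accuracy, b$val_accuracy)
  expect_identical(a$params, b$params)
  single <- spectrum_set(s$spectra, s$band_axis,
                         variety = rep("only", n_samples(s)))
  m <- build_cascadeseed(model_spec(24L, 2L), rng_seed = 1L)
  expect_error(train_model(m, single), "2 classes")
})

test_that("prediction ties break to the lowest class index", {
  m <- build_cascadeseed(model_spec(16L, 3L), rng_seed = 1L)
  m$params <- seedcascade:::tree_map(function(x) x * 0, m$params)
  m$classes <- c("a", "b", "c")
  p <- predict(m, matrix(runif(32), 2))
  expect_equal(p, c("a", "a"))
})

test_that("trained models survive the checkpoint round-trip", {
  m <- separable_fixture_model()
  stem <- withr::local_tempfile()
  save_cascadeseed(m, stem)
  back <- load_cascadeseed(stem)
  x <- separable_set(seed = 1L)$spectra[1:5, ]
  expect_equal(predict(back, x, type = "logit"), predict(m, x, type = "logit"),
               tolerance = 1e-12)
  expect_equal(back$classes, m$classes)
})
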