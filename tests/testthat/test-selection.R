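test_that("the identity-spectrum gradient matches central finite differences", {
  spec <- model_spec(20L, 3L)
  m <- build_cascadeseed(spec, rng_seed = 7L)
  set.seed(42)
  x <- runif(20)
  for (ci in 1:3) {
    lg <- seedcascade:::guided_loss_grad(m, x, ci, sparsity_weight = 1)
    eps <- 1e-5
    num <- vapply(1:20, function(j) {
      xp <- x; xm <- x
      xp[j] <- x[j] + eps; xm[j] <- x[j] - eps
      (seedcascade:::guided_loss_grad(m, xp, ci)$loss -
         seedcascade:::guided_loss_grad(m, xm, ci)$loss) / (2 * eps)
    }, numeric(1))
    rel <- sqrt(sum((num - lg$grad)^2)) / sqrt(sum(num^2))
    expect_lt(rel, 1e-4)
  }
})

test_that("guided optimization reduces the objective and is deterministic", {
  m <- planted_fixture_model(seed = 1L)
  cfg <- guided_config(iterations = 500L, rng_seed = 3L)
  id <- guided_identity_spectrum(m, 1L, cfg)
  expect_lt(id$final_loss, id$loss_trace[1])
  expect_length(id$x, m$spec$n_bands)
  id2 <- guided_identity_spectrum(m, 1L, cfg)
  expect_identical(id$x, id2$x)
  expect_error(guided_identity_spectrum(m, 5L, cfg), "out of range")
})

test_that("the L1 term sparsifies the optimized input", {
  m <- planted_fixture_model(seed = 1L)
  base <- guided_config(iterations = 400L, rng_seed = 9L)
  no_l1 <- base; no_l1$sparsity_weight <- 0
  with_l1 <- guided_identity_spectrum(m, 1L, base)
  without <- guided_identity_spectrum(m, 1L, no_l1)
  near_zero <- function(x) mean(abs(x) < 0.01 * max(abs(x)))
  expect_gt(near_zero(with_l1$x), near_zero(without$x))
})

test_that("without the L1 term the target logit rises above its initial value", {
  m <- planted_fixture_model(seed = 1L)
  cfg <- guided_config(iterations = 300L, sparsity_weight = 0, rng_seed = 4L)
  init <- seedcascade:::with_seed(cfg$rng_seed, runif(m$spec$n_bands))
  f0 <- predict(m, matrix(init, 1), type = "logit")[1, 1]
  id <- guided_identity_spectrum(m, 1L, cfg)
  f1 <- predict(m, matrix(id$x, 1), type = "logit")[1, 1]
  expect_gte(f1, f0)
})

test_that("peak extraction matches an exhaustive scan and is scale invariant", {
  spike <- numeric(12); spike[7] <- 1
  expect_equal(peaks_to_bands(spike), 7L)
  two <- numeric(12); two[c(3, 9)] <- 1
  expect_equal(peaks_to_bands(two), c(3L, 9L))
  expect_equal(peaks_to_bands(numeric(10)), integer(0))
  # 20-band vector with 5 planted peaks over a 5% noise floor
  set.seed(17)
  planted <- c(2L, 6L, 10L, 14L, 18L)
  v <- runif(20, 0, 0.05)
  v[planted] <- c(1, 0.9, 0.8, 0.7, 0.6)
  got <- peaks_to_bands(v, rel_threshold = 0.2, min_separation = 2L)
  # brute-force enumeration of qualifying local maxima
  oracle <- Filter(function(j) {
    lv <- if (j > 1) v[j - 1] else -Inf
    rv <- if (j < 20) v[j + 1] else -Inf
    v[j] >= lv && v[j] >= rv && v[j] > 0.2 * max(v)
  }, 1:20)
  expect_equal(got, as.integer(oracle))
  expect_equal(got, planted)
  expect_equal(peaks_to_bands(v * 37.5), got)
  expect_error(peaks_to_bands(v, rel_threshold = 1.5), "rel_threshold")
})

test_that("SPA projection chains agree with an explicit Gram-Schmidt oracle", {
  # mutually orthogonal columns: all are selected from any start
  X <- cbind(c(1, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 1.5, 0))
  for (s in 1:3) {
    expect_setequal(seedcascade:::spa_chain(X, s, 3L), 1:3)
  }
  # k = 1: the column of maximal norm
  set.seed(21)
  M <- matrix(rnorm(40), 8, 5)
  expect_equal(seedcascade:::spa_chain(M, which.max(colSums(M^2)), 1L),
               which.max(colSums(M^2)))
  # a duplicated column is never selected twice
  D <- cbind(M[, 1], M[, 1], M[, 2])
  chain <- seedcascade:::spa_chain(D, 1L, 3L)
  expect_false(any(duplicated(chain)))
  expect_false(all(c(1, 2) %in% chain))
  # 100 random 8x5 instances vs an independent Gram-Schmidt reference
  gs_oracle <- function(X, start, k) {
    chosen <- start
    basis <- list(X[, start] / sqrt(sum(X[, start]^2)))
    for (i in seq_len(k - 1L)) {
      resid <- X
      for (b in basis) resid <- resid - b %*% (t(b) %*% resid)
      norms <- colSums(resid^2)
      norms[chosen] <- -1
      nxt <- which.max(norms)
      chosen <- c(chosen, nxt)
      v <- resid[, nxt]
      basis <- c(basis, list(v / sqrt(sum(v^2))))
    }
    chosen
  }
  for (trial in 1:100) {
    X <- matrix(rnorm(40), 8, 5)
    s <- sample(5, 1)
    expect_equal(seedcascade:::spa_chain(X, s, 5L), gs_oracle(X, s, 5L))
  }
})

test_that("SPA subset selection scores candidates by cross-validated PLS-DA", {
  set <- planted_band_set(seed = 2L, n_per_cell = 40L)
  sel <- spa_select(set, max_k = 5L, label = "gm", cv_k = 5L, rng_seed = 2L)
  expect_lte(length(sel$indices), 5L)
  expect_false(is.unsorted(sel$indices))
  expect_true(all(sel$indices >= 1 & sel$indices <= 24))
  expect_gt(sel$score, 0.8)
  # the returned subset contains at least one planted band (+- 1)
  expect_true(any(vapply(sel$indices, function(i) {
    any(abs(c(4L, 10L, 16L, 22L) - i) <= 1)
  }, logical(1))))
})

test_that("guided_select unions per-class peaks with shared initialization", {
  m <- planted_fixture_model(seed = 1L)
  sel <- guided_select(m, guided_config(iterations = 400L, rng_seed = 5L))
  expect_s3_class(sel, "selection_result")
  expect_length(sel$per_class, 2L)
  expect_equal(sel$indices,
               sort(unique(unlist(sel$per_class, use.names = FALSE))))
  expect_equal(sel$centers, m$band_axis$values[sel$indices])
})

test_that("selection overlap reports coverage both ways under tolerance", {
  ax <- tiny_axis(20)
  a <- seedcascade:::new_selection_result("guided", "t", ax, c(3L, 8L, 15L))
  b <- seedcascade:::new_selection_result("SPA", "t", ax, c(3L, 8L, 15L))
  ov <- selection_overlap(a, b, 1L)
  expect_equal(ov$coverage_a_in_b, 1)
  expect_equal(ov$coverage_b_in_a, 1)
  d <- seedcascade:::new_selection_result("SPA", "t", ax, c(5L, 11L))
  ov0 <- selection_overlap(a, d, 0L)
  expect_equal(ov0$coverage_a_in_b, 0)
  expect_equal(ov0$n_matched, 0L)
  ax2 <- tiny_axis(10)
  e <- seedcascade:::new_selection_result("SPA", "t", ax2, 2L)
  expect_error(selection_overlap(a, e), "band axes")
})
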