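test_that("confusion matrices tabulate exactly", {
  cm <- confusion_matrix(rep(c("a", "b", "c"), each = 2),
                         rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(diag(cm)), c(2L, 2L, 2L))
  expect_equal(sum(cm), 6L)

  all0 <- confusion_matrix(c("a", "b", "b", "c"), rep("a", 4),
                           c("a", "b", "c"))
  expect_equal(unname(all0[, "a"]), unname(rowSums(all0)))

  set.seed(14)
  true <- sample(letters[1:4], 30, replace = TRUE)
  pred <- sample(letters[1:4], 30, replace = TRUE)
  got <- confusion_matrix(true, pred, letters[1:4])
  brute <- matrix(0L, 4, 4)
  for (i in 1:30) for (r in 1:4) for (c in 1:4) {
    if (true[i] == letters[r] && pred[i] == letters[c]) {
      brute[r, c] <- brute[r, c] + 1L
    }
  }
  expect_equal(unclass(got), brute, ignore_attr = TRUE)
  expect_error(confusion_matrix("a", "z", c("a", "b")), "unknown label")
})

test_that("metrics reproduce a hand-evaluated two-class tabulation", {
  # counts with TP = (3, 1), FP = (1, 3), FN = (3, 1)
  cm <- matrix(c(3L, 1L, 3L, 1L), 2, 2,
               dimnames = list(true = c("x", "y"), predicted = c("x", "y")))
  ct <- seedcascade:::cm_counts(cm)
  expect_equal(unname(ct$tp), c(3, 1))
  expect_equal(unname(ct$fp), c(1, 3))
  expect_equal(unname(ct$fn), c(3, 1))
  rep <- classification_metrics(cm)
  expect_equal(unname(rep$f1), c(0.6, 1 / 3), tolerance = 1e-12)
  expect_equal(rep$macro_f1, 0.4667, tolerance = 1e-4)
})

test_that("perfect predictions give unit metrics; micro F1 equals accuracy", {
  perfect <- evaluate_predictions(c("a", "b", "b"), c("a", "b", "b"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$micro_f1, 1)
  set.seed(15)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(5:40, 1)
    true <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    r <- evaluate_predictions(true, pred, letters[1:k])
    expect_equal(r$micro_f1, r$accuracy, tolerance = 1e-12)
    expect_true(all(unlist(r[c("accuracy", "precision", "recall", "f1",
                               "macro_f1", "micro_f1")]) >= 0))
    expect_true(all(unlist(r[c("accuracy", "precision", "recall", "f1",
                               "macro_f1", "micro_f1")]) <= 1))
    # macro F1 = 1 iff the matrix is diagonal
    expect_equal(r$macro_f1 == 1,
                 sum(diag(r$confusion)) == sum(r$confusion) &&
                   all(diag(r$confusion) > 0))
  }
})

test_that("zero-denominator classes score 0 and are flagged", {
  r <- evaluate_predictions(c("a", "a", "b"), c("a", "a", "a"),
                            c("a", "b", "c"))
  expect_equal(unname(r$precision["c"]), 0)
  expect_true(all(c("b", "c") %in% r$zero_denominator))
})

test_that("PCA scores match a dense eigendecomposition oracle", {
  # variance along a single direction
  t_val <- seq(-1, 1, length.out = 10)
  x1 <- t_val %o% c(1, 2, 3)
  p1 <- pca_scores(x1, 1)
  expect_equal(p1$explained[1], 1)
  set.seed(16)
  x <- matrix(rnorm(24), 6, 4)
  p <- pca_scores(x, 3)
  # orthogonal score columns
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))
  # eigen oracle up to sign
  x0 <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(x0) / (6 - 1))
  for (j in 1:3) {
    ref <- x0 %*% ev$vectors[, j]
    expect_equal(abs(unname(p$scores[, j])), abs(as.numeric(ref)),
                 tolerance = 1e-8)
  }
  expect_equal(p$explained,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-8)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  expect_error(pca_scores(matrix(1, 5, 3), 1), "degenerate")
  expect_error(pca_scores(x, 6), "n_components")
})

test_that("cross-variety matrices evaluate every model on every test set", {
  ax <- tiny_axis(16)
  # constant-class model: zeroed weights always predict the first class
  m <- build_cascadeseed(model_spec(16L, 2L), rng_seed = 1)
  m$params <- seedcascade:::tree_map(function(x) x * 0, m$params)
  m$classes <- c("GM", "non-GM")
  balanced <- spectrum_set(matrix(runif(6 * 16), 6), ax,
                           gm = rep(c("GM", "non-GM"), 3))
  out <- cross_variety_matrix(list(v1 = m), list(v1 = balanced))
  expect_equal(dim(out), c(1L, 1L))
  expect_equal(out[1, 1], 0.5)
  bad <- spectrum_set(matrix(runif(6 * 10), 6), tiny_axis(10),
                      gm = rep(c("GM", "non-GM"), 3))
  expect_error(cross_variety_matrix(list(v1 = m),
                                    list(v1 = balanced, v2 = bad)),
               "band axes")
})
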