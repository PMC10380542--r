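# Characteristic-wavelength selection: activation maximization of a trained
# CascadeSeed model (guided backpropagation with an L1 sparsity penalty)
# and the successive projections algorithm (SPA) baseline.

#' Configuration for guided identity-spectrum optimization
#'
#' @param learning_rate Gradient step size on the input vector (default 6).
#' @param iterations Number of gradient steps (default 15,000; use fewer
#'   for desk-scale runs).
#' @param sparsity_weight Multiplier on the L1 term (default 1; 0 disables
#'   sparsity).
#' @param signed_sum If `TRUE`, use the literal signed sum of the input
#'   entries instead of the L1 penalty.
#' @param rng_seed Seed for the uniform \[0, 1\] initialization; the same
#'   seeded noise vector is reused across classes of one model.
#' @return A list of class `guided_config`.
#' @export
guided_config <- function(learning_rate = 6, iterations = 15000L,
                          sparsity_weight = 1, signed_sum = FALSE,
                          rng_seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (iterations < 1) stop("`iterations` must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 sparsity_weight = sparsity_weight,
                 signed_sum = isTRUE(signed_sum),
                 rng_seed = as.integer(rng_seed)),
            class = "guided_config")
}

# Loss and input gradient of the identity-spectrum objective
# L_C(x) = -f_C(x) + sum_{i != C} f_i(x) + sw * sum_j |x_j|,
# with f the model's pre-softmax class outputs and parameters frozen.
guided_loss_grad <- function(model, x, class_idx, sparsity_weight = 1,
                             signed_sum = FALSE) {
  spec <- model$spec
  X <- matrix(x, nrow = 1L)
  fw <- cascadeseed_forward(model$params, spec, X, cache = TRUE)
  f <- as.numeric(fw$logits)
  dlogits <- matrix(1, 1L, spec$n_classes)
  dlogits[1L, class_idx] <- -1
  bk <- cascadeseed_backward(model$params, spec, fw, dlogits,
                             need_param_grads = FALSE, need_input_grad = TRUE)
  if (signed_sum) {
    pen <- sparsity_weight * sum(x)
    pen_grad <- rep(sparsity_weight, length(x))
  } else {
    pen <- sparsity_weight * sum(abs(x))
    pen_grad <- sparsity_weight * sign(x)
  }
  list(loss = -f[class_idx] + sum(f[-class_idx]) + pen,
       grad = as.numeric(bk$dX) + pen_grad,
       logits = f)
}

#' Optimize a class identity spectrum by guided backpropagation
#'
#' Starting from a seeded uniform \[0, 1\] noise vector, the input is
#' updated by plain gradient descent on
#' `L_C(x) = -f_C(x) + sum_(i != C) f_i(x) + sw * sum_j |x_j|`
#' with the model's parameters frozen: the target class output is driven
#' up, the off-class outputs down, and the L1 term sparsifies the input so
#' only influential bands stay large.
#'
#' @param model A trained `cascadeseed`.
#' @param class_idx Target class index `C` (1-based) or class label.
#' @param cfg A [guided_config()].
#' @param init Optional explicit initialization vector (overrides the
#'   seeded noise; used to share one fixed noise vector across classes).
#' @return An object of class `identity_spectrum`: `x` (optimized vector),
#'   `class_idx`, `class_label`, `loss_trace`, `final_loss`.
#' @export
guided_identity_spectrum <- function(model, class_idx, cfg = guided_config(),
                                     init = NULL) {
  spec <- model$spec
  if (is.character(class_idx)) {
    ci <- match(class_idx, model$classes)
    if (is.na(ci)) stop("unknown class label: ", class_idx, call. = FALSE)
    class_idx <- ci
  }
  if (class_idx < 1L || class_idx > spec$n_classes) {
    stop("`class_idx` out of range", call. = FALSE)
  }
  x <- if (is.null(init)) {
    with_seed(cfg$rng_seed, stats::runif(spec$n_bands))
  } else {
    if (length(init) != spec$n_bands) stop("bad `init` length", call. = FALSE)
    as.numeric(init)
  }
  trace <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    lg <- guided_loss_grad(model, x, class_idx, cfg$sparsity_weight,
                           cfg$signed_sum)
    if (!is.finite(lg$loss)) {
      stop(sprintf("divergence: non-finite loss at iteration %d", it),
           call. = FALSE)
    }
    trace[it] <- lg$loss
    x <- x - cfg$learning_rate * lg$grad
  }
  structure(list(x = x,
                 class_idx = class_idx,
                 class_label = if (!is.null(model$classes))
                   model$classes[class_idx] else as.character(class_idx),
                 loss_trace = trace,
                 final_loss = trace[length(trace)]),
            class = "identity_spectrum")
}

#' Extract characteristic band indices from an identity spectrum
#'
#' Local maxima of `|x|` exceeding `rel_threshold * max(|x|)`, kept
#' greedily in descending amplitude subject to a pairwise index separation
#' of at least `min_separation`.
#'
#' @param identity An `identity_spectrum` (or bare numeric vector).
#' @param rel_threshold Relative amplitude threshold in (0, 1).
#' @param min_separation Minimum index distance between kept peaks.
#' @return Sorted integer band indices (empty for an all-zero input).
#' @export
peaks_to_bands <- function(identity, rel_threshold = 0.2, min_separation = 2L) {
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    stop("`rel_threshold` must be in (0, 1)", call. = FALSE)
  }
  v <- abs(if (inherits(identity, "identity_spectrum")) identity$x else
    as.numeric(identity))
  B <- length(v)
  if (max(v) == 0) return(integer(0))
  left <- c(-Inf, v[-B])
  right <- c(v[-1], -Inf)
  cand <- which(v >= left & v >= right & v > rel_threshold * max(v))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (j in cand) {
    if (!length(kept) || min(abs(kept - j)) >= min_separation) {
      kept <- c(kept, j)
    }
  }
  sort(kept)
}

new_selection_result <- function(method, task, band_axis, indices,
                                 per_class = NULL, identity = NULL,
                                 score = NULL) {
  indices <- sort(unique(as.integer(indices)))
  structure(list(method = method, task = task,
                 band_axis = band_axis,
                 indices = indices,
                 centers = band_axis$values[indices],
                 per_class = per_class, identity = identity, score = score),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s / %s: %d bands\n  %s %s\n",
              x$method, x$task, length(x$indices),
              paste(signif(x$centers, 5), collapse = ", "),
              band_unit(x$band_axis)))
  invisible(x)
}

#' Guided-backpropagation band selection for a model
#'
#' Runs [guided_identity_spectrum()] for every class of the model with the
#' same seeded noise initialization, extracts peaks per class with
#' [peaks_to_bands()], and returns the sorted union with per-class
#' provenance.
#'
#' @param model A trained `cascadeseed` (with a `band_axis` attached, or
#'   pass one explicitly).
#' @param cfg A [guided_config()].
#' @param rel_threshold,min_separation Passed to [peaks_to_bands()].
#' @param band_axis Band axis of the model's input (defaults to
#'   `model$band_axis`).
#' @param task Free-text task tag recorded in the result.
#' @return A `selection_result` with `per_class` peak lists and the
#'   per-class identity spectra.
#' @export
guided_select <- function(model, cfg = guided_config(), rel_threshold = 0.2,
                          min_separation = 2L, band_axis = model$band_axis,
                          task = "variety") {
  if (is.null(band_axis)) stop("no band axis available", call. = FALSE)
  init <- with_seed(cfg$rng_seed, stats::runif(model$spec$n_bands))
  ids <- lapply(seq_len(model$spec$n_classes), function(ci) {
    guided_identity_spectrum(model, ci, cfg, init = init)
  })
  per_class <- lapply(ids, peaks_to_bands, rel_threshold = rel_threshold,
                      min_separation = min_separation)
  names(per_class) <- vapply(ids, `[[`, "", "class_label")
  new_selection_result("guided", task, band_axis,
                       unlist(per_class, use.names = FALSE),
                       per_class = per_class, identity = ids)
}

# Successive-projections chain from one starting column: repeatedly append
# the band whose (centered) column has maximal norm after orthogonal
# projection onto the complement of the chosen columns.
spa_chain <- function(X, start, max_k) {
  B <- ncol(X)
  R <- X
  chain <- integer(max_k)
  chain[1L] <- start
  for (step in seq_len(max_k - 1L)) {
    v <- R[, chain[step]]
    nv2 <- sum(v^2)
    if (nv2 < 1e-12) return(chain[seq_len(step)])
    R <- R - v %*% (crossprod(v, R) / nv2)
    norms <- colSums(R^2)
    norms[chain[seq_len(step)]] <- -1
    nxt <- which.max(norms)
    if (norms[nxt] < 1e-12) return(chain[seq_len(step)])
    chain[step + 1L] <- nxt
  }
  chain
}

#' Successive projections algorithm band selection
#'
#' For each starting band, a projection chain of up to `max_k` bands is
#' grown on the column-centered training spectra; every prefix of every
#' chain is scored by the evaluator (default: PLS-DA pooled accuracy under
#' stratified cross-validation) and the best-scoring subset is returned
#' (ties: smaller subset, then lexicographic order).
#'
#' @param train A labeled `spectrum_set`.
#' @param max_k Maximum number of selected bands (default 13).
#' @param label Label defining the classes.
#' @param cv_k Cross-validation folds for the evaluator.
#' @param n_latent PLS-DA latent variables for the evaluator (capped at the
#'   subset size).
#' @param n_starts Number of starting bands; defaults to all bands (capped
#'   at a seeded random subset of 256 for very wide spectra).
#' @param rng_seed Seed (start subsampling and CV folds).
#' @param evaluator Optional function `(spectrum_set, indices) -> accuracy`
#'   replacing the PLS-DA cross-validation scorer.
#' @return A `selection_result` (score = evaluator accuracy).
#' @export
spa_select <- function(train, max_k = 13L, label = c("variety", "gm"),
                       cv_k = 10L, n_latent = 5L, n_starts = NULL,
                       rng_seed = 1L, evaluator = NULL) {
  label <- match.arg(label)
  if (max_k < 1L) stop("`max_k` must be >= 1", call. = FALSE)
  B <- n_bands(train$band_axis)
  max_k <- min(max_k, B)
  X <- sweep(train$spectra, 2, colMeans(train$spectra))
  starts <- seq_len(B)
  if (is.null(n_starts)) n_starts <- if (B > 256L) 256L else B
  if (n_starts < B) starts <- with_seed(rng_seed, sort(sample(B, n_starts)))
  if (is.null(evaluator)) {
    y_all <- split_label(train, label)
    folds <- stratified_folds(y_all, cv_k, rng_seed)
    evaluator <- function(set, idx) {
      x_sub <- set$spectra[, idx, drop = FALSE]
      correct <- 0L
      for (f in seq_len(cv_k)) {
        te <- which(folds == f); tr <- which(folds != f)
        nl <- min(n_latent, length(idx), length(tr) - 1L)
        m <- plsda_fit(list(x = x_sub[tr, , drop = FALSE], y = y_all[tr]),
                       n_latent = nl)
        p <- plsda_predict(m, x_sub[te, , drop = FALSE])
        correct <- correct + sum(p == y_all[te])
      }
      correct / length(y_all)
    }
  }
  best <- list(score = -Inf, subset = integer(0))
  for (s in starts) {
    chain <- spa_chain(X, s, max_k)
    for (k in seq_along(chain)) {
      subset <- sort(chain[seq_len(k)])
      score <- evaluator(train, subset)
      better <- score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
           (length(subset) < length(best$subset) ||
              (length(subset) == length(best$subset) &&
                 lex_less(subset, best$subset))))
      if (better) best <- list(score = score, subset = subset)
    }
  }
  new_selection_result("SPA", label, train$band_axis, best$subset,
                       score = best$score)
}

lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

#' Overlap report between two band selections
#'
#' Matches indices under an index tolerance and reports the intersection
#' size and coverage fractions both ways.
#'
#' @param a,b `selection_result`s on the same band axis.
#' @param tolerance_index Two indices match if they differ by at most this.
#' @return A list: `n_matched`, `coverage_a_in_b`, `coverage_b_in_a`,
#'   `matched_a`, `matched_b`.
#' @export
selection_overlap <- function(a, b, tolerance_index = 1L) {
  if (!axes_identical(a$band_axis, b$band_axis)) {
    stop("selections are on different band axes", call. = FALSE)
  }
  ia <- a$indices; ib <- b$indices
  matched_a <- vapply(ia, function(i) any(abs(ib - i) <= tolerance_index),
                      logical(1))
  matched_b <- vapply(ib, function(i) any(abs(ia - i) <= tolerance_index),
                      logical(1))
  list(n_matched = sum(matched_a),
       coverage_a_in_b = if (length(ia)) mean(matched_a) else NA_real_,
       coverage_b_in_a = if (length(ib)) mean(matched_b) else NA_real_,
       matched_a = ia[matched_a], matched_b = ib[matched_b])
}
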