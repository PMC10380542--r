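# Multiclass evaluation: confusion matrices, accuracy, macro/micro F1,
# PCA score decomposition and the cross-variety GM transfer matrix.

#' Tabulate a confusion matrix
#'
#' Rows are true classes, columns predicted classes, in `class_names`
#' order.
#'
#' @param true_labels,predicted_labels Equal-length label vectors, all
#'   values in `class_names`.
#' @param class_names Class name order; defaults to the sorted union of
#'   the labels.
#' @return An integer matrix of class `conf_mat`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             class_names = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (is.null(class_names)) {
    class_names <- sort(unique(c(true_labels, predicted_labels)))
  }
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(unknown)) {
    stop("unknown label: \"", unknown[1], "\"", call. = FALSE)
  }
  k <- length(class_names)
  cm <- matrix(0L, k, k, dimnames = list(true = class_names,
                                         predicted = class_names))
  ti <- match(true_labels, class_names)
  pi <- match(predicted_labels, class_names)
  for (i in seq_along(ti)) cm[ti[i], pi[i]] <- cm[ti[i], pi[i]] + 1L
  structure(cm, class = c("conf_mat", "matrix", "array"))
}

cm_counts <- function(cm) {
  tp <- diag(cm)
  list(tp = tp, fp = colSums(cm) - tp, fn = rowSums(cm) - tp)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)` and recall `TP/(TP+FN)`; macro F1 is
#' the unweighted mean of per-class F1 over all `N` tabulated classes;
#' micro F1 pools TP/FP/FN over classes (and equals accuracy for
#' single-label classification). Empty denominators yield 0 and are
#' flagged.
#'
#' @param cm A `conf_mat` (or square count matrix with dimnames).
#' @return A list of class `eval_report`: `accuracy`, `precision`,
#'   `recall`, `f1`, `macro_f1`, `micro_f1`, `n_classes`,
#'   `confusion`, `zero_denominator` (flagged class names).
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0) {
    stop("`cm` must be a non-empty square confusion matrix", call. = FALSE)
  }
  ct <- cm_counts(cm)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(ct$tp, ct$tp + ct$fp)
  recall <- safe_div(ct$tp, ct$tp + ct$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  micro_p <- sum(ct$tp) / sum(ct$tp + ct$fp)
  micro_r <- sum(ct$tp) / sum(ct$tp + ct$fn)
  micro_f1 <- if (micro_p + micro_r > 0) {
    2 * micro_p * micro_r / (micro_p + micro_r)
  } else 0
  flagged <- rownames(cm)[(ct$tp + ct$fp) == 0 | (ct$tp + ct$fn) == 0]
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 precision = precision, recall = recall, f1 = f1,
                 macro_f1 = mean(f1),
                 micro_f1 = micro_f1,
                 n_classes = nrow(cm), confusion = cm,
                 zero_denominator = flagged),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d classes, accuracy %.4f, macro F1 %.4f, micro F1 %.4f\n",
              x$n_classes, x$accuracy, x$macro_f1, x$micro_f1))
  print(x$confusion)
  invisible(x)
}

#' Evaluate predictions against true labels
#'
#' Convenience wrapper: tabulates the confusion matrix and computes the
#' metric report.
#'
#' @inheritParams confusion_matrix
#' @return An `eval_report`.
#' @export
evaluate_predictions <- function(true_labels, predicted_labels,
                                 class_names = NULL) {
  classification_metrics(
    confusion_matrix(true_labels, predicted_labels, class_names))
}

#' PCA score decomposition of a spectrum set
#'
#' Mean-centered projection onto the leading eigenvectors of the band
#' covariance. The sign of each component is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param set A `spectrum_set` (or numeric matrix).
#' @param n_components Number of components (default 2).
#' @return A list: `scores` (n x n_components), `loadings`,
#'   `explained` (variance fractions, non-increasing).
#' @export
pca_scores <- function(set, n_components = 2L) {
  x <- if (inherits(set, "spectrum_set")) set$spectra else as.matrix(set)
  n <- nrow(x)
  if (n_components > min(n - 1L, ncol(x))) {
    stop("`n_components` exceeds min(n_samples - 1, n_bands)", call. = FALSE)
  }
  if (all(apply(x, 2, stats::var) == 0)) {
    stop("degenerate input: all bands are constant", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE], 2,
                    flip, `*`)
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  list(scores = scores, loadings = loadings, explained = explained)
}

#' Cross-variety GM transfer matrix
#'
#' Entry (i, j) is the accuracy of variety i's GM model evaluated on
#' variety j's test set: the diagonal is in-variety performance, the
#' off-diagonal measures how a GM model transfers to other genetic
#' backgrounds.
#'
#' @param gm_registry Named list of trained binary GM models (as in a
#'   [cascade_model()]).
#' @param test_sets Named list of `spectrum_set`s with `gm` labels, one per
#'   variety, sharing one band axis.
#' @return A numeric accuracy matrix (rows: model variety; columns: test
#'   variety).
#' @export
cross_variety_matrix <- function(gm_registry, test_sets) {
  axes <- lapply(test_sets, function(s) s$band_axis)
  for (ax in axes[-1]) {
    if (!axes_identical(axes[[1]], ax)) {
      stop("test sets are on different band axes", call. = FALSE)
    }
  }
  models <- names(gm_registry)
  tests <- names(test_sets)
  out <- matrix(NA_real_, length(models), length(tests),
                dimnames = list(model = models, test = tests))
  for (i in models) for (j in tests) {
    p <- predict(gm_registry[[i]], test_sets[[j]])
    out[i, j] <- mean(p == test_sets[[j]]$gm)
  }
  out
}
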