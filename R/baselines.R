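# Benchmark chemometric classifiers and evaluation protocols: PLS-DA,
# one-vs-rest RBF-SVM, the stratified 7:3 split and 10-fold CV.

#' Stratified train/test split
#'
#' Seeded, stratified partition of a spectrum set: per class,
#' `round(ratio * n_class)` samples (at least 1, at most `n_class - 1`)
#' go to the training side.
#'
#' @param set A `spectrum_set` with labels.
#' @param ratio Training fraction (default 0.7).
#' @param stratified Stratify by the chosen label (default `TRUE`).
#' @param rng_seed Seed; identical seeds give identical plans.
#' @param label Which label to stratify on: `"variety"`, `"gm"`, or
#'   `"cell"` (the variety x GM interaction).
#' @return A list of class `split_plan`: `train`, `test` index vectors plus
#'   the call parameters.
#' @export
split_dataset <- function(set, ratio = 0.7, stratified = TRUE, rng_seed = 1L,
                          label = c("cell", "variety", "gm")) {
  label <- match.arg(label)
  y <- split_label(set, label)
  n <- n_samples(set)
  with_seed(rng_seed, {
    if (stratified) {
      if (any(table(y) < 2L)) {
        stop("every class needs >= 2 samples for a stratified split",
             call. = FALSE)
      }
      train <- unlist(lapply(split(seq_len(n), y), function(ck) {
        nt <- min(max(1L, round(ratio * length(ck))), length(ck) - 1L)
        sample(ck, nt)
      }), use.names = FALSE)
    } else {
      train <- sample(n, min(max(1L, round(ratio * n)), n - 1L))
    }
    train <- sort(train)
    structure(list(train = train, test = setdiff(seq_len(n), train),
                   ratio = ratio, stratified = stratified,
                   rng_seed = as.integer(rng_seed)),
              class = "split_plan")
  })
}

split_label <- function(set, label) {
  switch(label,
         variety = set$variety,
         gm = set$gm,
         cell = if (is.null(set$gm)) set$variety else
           paste(set$variety, set$gm, sep = "-")) -> y
  if (is.null(y)) stop("set lacks the `", label, "` labels", call. = FALSE)
  y
}

#' Fit a PLS-DA classifier
#'
#' Partial least squares (NIPALS PLS2) regression of one-hot class targets
#' on column-centered spectra with `n_latent` components; prediction is the
#' argmax of the fitted response (ties to the lowest class index).
#'
#' @param train A `spectrum_set` with labels, or `list(x, y)`.
#' @param n_latent Number of latent variables (default 5).
#' @param label Label to fit when `train` is a `spectrum_set`.
#' @return An object of class `plsda_model`.
#' @export
plsda_fit <- function(train, n_latent = 5L, label = c("variety", "gm")) {
  label <- match.arg(label)
  if (inherits(train, "spectrum_set")) {
    x <- train$spectra; y <- split_label(train, label)
  } else {
    x <- as.matrix(train$x); y <- as.character(train$y)
  }
  classes <- sort(unique(y))
  n <- nrow(x); B <- ncol(x)
  if (n_latent > min(n - 1L, B)) {
    stop(sprintf("`n_latent` = %d exceeds min(n_samples - 1, n_bands) = %d",
                 n_latent, min(n - 1L, B)), call. = FALSE)
  }
  Y <- outer(y, classes, `==`) * 1
  x_mean <- colMeans(x); y_mean <- colMeans(Y)
  X0 <- sweep(x, 2, x_mean)
  Y0 <- sweep(Y, 2, y_mean)
  E <- X0; F <- Y0
  W <- matrix(0, B, n_latent)   # X weights
  P <- matrix(0, B, n_latent)   # X loadings
  Q <- matrix(0, length(classes), n_latent)  # Y loadings
  for (a in seq_len(n_latent)) {
    u <- F[, which.max(colSums(F^2))]
    w <- t_old <- NULL
    for (it in seq_len(500L)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t_sc <- E %*% w
      q <- crossprod(F, t_sc) / sum(t_sc^2)
      u_new <- F %*% q / sum(q^2)
      if (!is.null(t_old) && sum((t_sc - t_old)^2) < 1e-12 * sum(t_sc^2)) {
        u <- u_new
        break
      }
      t_old <- t_sc
      u <- u_new
    }
    t_sc <- E %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-14) {
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[, seq_len(a - 1L), drop = FALSE]
      break
    }
    p <- crossprod(E, t_sc) / tt
    q <- crossprod(F, t_sc) / tt
    W[, a] <- w; P[, a] <- p; Q[, a] <- q
    E <- E - t_sc %*% t(p)
    F <- F - t_sc %*% t(q)
  }
  # regression coefficients B = W (P'W)^-1 Q'
  coefs <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(coefs = coefs, x_mean = x_mean, y_mean = y_mean,
                 classes = classes, n_latent = ncol(W),
                 scores_basis = W, loadings = P),
            class = "plsda_model")
}

#' Predict classes from a PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param newdata Numeric spectra matrix or a `spectrum_set`.
#' @param type `"class"` or `"response"` (fitted one-hot scores).
#' @return Labels, or the fitted response matrix.
#' @export
plsda_predict <- function(model, newdata, type = c("class", "response")) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "spectrum_set")) newdata$spectra else as.matrix(newdata)
  resp <- sweep(x, 2, model$x_mean) %*% model$coefs
  resp <- sweep(resp, 2, model$y_mean, `+`)
  colnames(resp) <- model$classes
  if (type == "response") return(resp)
  model$classes[max.col(resp, ties.method = "first")]
}

#' Fit a one-vs-rest RBF-SVM classifier
#'
#' One binary radial-basis SVM per class (shared `C` and kernel width); the
#' class with the maximum decision value wins. The default kernel width is
#' the variance-scaled heuristic `1 / (n_bands * var(x))`.
#'
#' @param train A `spectrum_set` with labels, or `list(x, y)`.
#' @param C Regularization parameter (default 100).
#' @param gamma RBF width; `NULL` for the variance-scaled default.
#' @param label Label to fit when `train` is a `spectrum_set`.
#' @return An object of class `ovr_svm_model`.
#' @export
svm_fit <- function(train, C = 100, gamma = NULL, label = c("variety", "gm")) {
  label <- match.arg(label)
  if (inherits(train, "spectrum_set")) {
    x <- train$spectra; y <- split_label(train, label)
  } else {
    x <- as.matrix(train$x); y <- as.character(train$y)
  }
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (is.null(gamma)) {
    v <- stats::var(as.numeric(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  machines <- lapply(classes, function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(x, yb, type = "C-classification", kernel = "radial",
               cost = C, gamma = gamma, scale = FALSE)
  })
  names(machines) <- classes
  structure(list(machines = machines, classes = classes, C = C, gamma = gamma),
            class = "ovr_svm_model")
}

#' Predict classes from a one-vs-rest SVM
#'
#' @param model An `ovr_svm_model`.
#' @param newdata Numeric spectra matrix or a `spectrum_set`.
#' @return Predicted labels (max decision value across the binary machines).
#' @export
svm_predict <- function(model, newdata) {
  x <- if (inherits(newdata, "spectrum_set")) newdata$spectra else as.matrix(newdata)
  dec <- vapply(model$classes, function(cl) {
    p <- stats::predict(model$machines[[cl]], x, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # orient so that larger means "pos"
    if (grepl("^pos/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) dec <- matrix(dec, nrow = 1L)
  model$classes[max.col(dec, ties.method = "first")]
}

# Seeded stratified fold assignment; fold sizes differ by at most one.
stratified_folds <- function(y, k, rng_seed) {
  with_seed(rng_seed, {
    folds <- integer(length(y))
    offset <- 0L
    for (cl in sort(unique(y))) {
      ck <- sample(which(y == cl))
      # rotate the starting fold between classes to balance fold sizes
      folds[ck] <- ((seq_along(ck) - 1L + offset) %% k) + 1L
      offset <- (offset + length(ck)) %% k
    }
    folds
  })
}

#' Stratified k-fold cross-validation
#'
#' Builds seeded stratified folds (sizes differing by at most one per
#' class), fits with `fit_fun` on each training complement and pools the
#' out-of-fold predictions.
#'
#' @param set A `spectrum_set`.
#' @param fit_fun Function `(spectrum_set) -> model`.
#' @param predict_fun Function `(model, spectrum_set) -> labels`.
#' @param k Number of folds (default 10).
#' @param rng_seed Seed for fold assignment.
#' @param label Label defining classes (and stratification).
#' @return A list: `fold_accuracy`, `pooled_accuracy`, `predictions`
#'   (in sample order), `folds` (fold id per sample).
#' @export
crossval <- function(set, fit_fun, predict_fun, k = 10L, rng_seed = 1L,
                     label = c("variety", "gm")) {
  label <- match.arg(label)
  y <- split_label(set, label)
  n <- n_samples(set)
  if (k > n) stop("`k` cannot exceed the number of samples", call. = FALSE)
  folds <- stratified_folds(y, k, rng_seed)
  with_seed(rng_seed, {
    preds <- character(n)
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      te <- which(folds == f)
      tr <- which(folds != f)
      model <- fit_fun(subset_samples(set, tr))
      p <- as.character(predict_fun(model, subset_samples(set, te)))
      preds[te] <- p
      fold_acc[f] <- mean(p == y[te])
    }
    list(fold_accuracy = fold_acc, pooled_accuracy = mean(preds == y),
         predictions = preds, folds = folds)
  })
}
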