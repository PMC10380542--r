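# CascadeSeed: a 1-D multireceptive-field convolutional network for
# spectral classification. The conv and pooling kernels live in compiled
# code (src/conv1d.cpp); activations are stored channels x (n*L), sample i
# occupying the contiguous column block (i-1)*L + 1 .. i*L.

pool_len <- function(L) (L - 1L) %/% 2L + 1L  # kernel 3, stride 2, pad 1

tap_offsets <- function(k) seq_len(k) - (k + 1L) %/% 2L

conv_fwd <- function(A, taps, bias, n, L) {
  conv1d_fwd_cpp(A, taps, tap_offsets(length(taps)), bias, n, L)
}

conv_bwd <- function(dOut, A, taps, n, L, need_param_grads = TRUE) {
  conv1d_bwd_cpp(dOut, A, taps, tap_offsets(length(taps)), n, L,
                 need_param_grads)
}

# Multireceptive-field module: parallel convs with kernels 1/3/5/7 summed
# elementwise. The sum equals one kernel-7 conv whose tap weights are the
# sums of the per-kernel taps, so forward/backward run on effective taps;
# per-conv parameters are kept so each kernel keeps its own fan-in at init.
mrf_eff <- function(mp) {
  kernels <- as.integer(sub("^c", "", names(mp$W)))
  hmax <- (max(kernels) - 1L) %/% 2L
  taps <- vector("list", 2L * hmax + 1L)
  for (t in -hmax:hmax) {
    acc <- NULL
    for (ci in seq_along(kernels)) {
      h <- (kernels[ci] - 1L) %/% 2L
      if (abs(t) <= h) {
        w <- mp$W[[ci]][[t + h + 1L]]
        acc <- if (is.null(acc)) w else acc + w
      }
    }
    taps[[t + hmax + 1L]] <- acc
  }
  list(taps = taps, bias = Reduce(`+`, mp$b))
}

mrf_scatter_grads <- function(mp, dW_eff, db_eff) {
  kernels <- as.integer(sub("^c", "", names(mp$W)))
  hmax <- (max(kernels) - 1L) %/% 2L
  gW <- vector("list", length(kernels)); names(gW) <- names(mp$W)
  for (ci in seq_along(kernels)) {
    h <- (kernels[ci] - 1L) %/% 2L
    gW[[ci]] <- lapply(-h:h, function(t) dW_eff[[t + hmax + 1L]])
  }
  gb <- lapply(seq_along(kernels), function(i) db_eff)
  names(gb) <- names(mp$b)
  list(W = gW, b = gb)
}

maxpool_fwd <- function(A, n, L) maxpool1d_fwd_cpp(A, n, L)

maxpool_bwd <- function(dOut, cache, n, L) {
  maxpool1d_bwd_cpp(dOut, cache$which_tap, n, L)
}

# C x (n*L2) activation matrix -> n x (C*L2) flat feature matrix (channel
# index varying fastest within each position)
flatten_act <- function(A, n, L2) {
  t(matrix(A, nrow = nrow(A) * L2, ncol = n))
}

unflatten_act <- function(F, n, L2, C) {
  matrix(t(F), nrow = C, ncol = n * L2)
}

#' Architecture specification for a CascadeSeed model
#'
#' Module 1 applies four parallel 1-D convolutions (kernel sizes 1/3/5/7,
#' `m1_filters` each, stride 1, "same" padding) to the one-channel input
#' spectrum and sums them; the summed map is rectified and concatenated
#' with the original spectrum along the channel axis. Module 2 repeats the
#' pattern with `m2_filters` filters on the concatenated tensor. Two common
#' convolutions (kernel 3) with `common_filters` filters follow, each
#' trailed by a max-pooling (kernel 3, stride 2, padding 1), then a single
#' affine head maps the flattened features to class scores.
#'
#' @param n_bands Input spectrum length (>= 8 so that two poolings are
#'   well defined).
#' @param n_classes Number of output classes (>= 2).
#' @param m1_filters,m2_filters,common_filters Filter counts (defaults
#'   128, 64 and c(64, 32)).
#' @param kernels Parallel kernel sizes of the multireceptive-field modules.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(n_bands, n_classes, m1_filters = 128L,
                       m2_filters = 64L, common_filters = c(64L, 32L),
                       kernels = c(1L, 3L, 5L, 7L)) {
  if (n_bands < 8L) stop("invalid architecture: `n_bands` must be >= 8", call. = FALSE)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (any(kernels %% 2 == 0)) stop("kernel sizes must be odd", call. = FALSE)
  L1 <- pool_len(n_bands)
  L2 <- pool_len(L1)
  if (L2 < 1L) stop("invalid architecture: spectrum too short for two poolings",
                    call. = FALSE)
  structure(list(n_bands = as.integer(n_bands), n_classes = as.integer(n_classes),
                 m1_filters = as.integer(m1_filters),
                 m2_filters = as.integer(m2_filters),
                 common_filters = as.integer(common_filters),
                 kernels = as.integer(kernels),
                 pooled_len = c(L1, L2),
                 flat_dim = as.integer(common_filters[2] * L2)),
            class = "model_spec")
}

#' Tabulate the tensor shapes of a CascadeSeed architecture
#'
#' @param spec A [model_spec()].
#' @param batch Batch size used in the tabulation.
#' @return A data frame with one row per layer: layer name, input/output
#'   channels and spatial length.
#' @export
cascadeseed_shapes <- function(spec, batch = 256L) {
  L <- spec$n_bands
  L1 <- spec$pooled_len[1]; L2 <- spec$pooled_len[2]
  data.frame(
    layer = c(sprintf("module1_conv_k%d", spec$kernels),
              "module1_sum", "concat",
              sprintf("module2_conv_k%d", spec$kernels),
              "module2_sum", "common_conv1", "pool1", "common_conv2",
              "pool2", "flatten", "head"),
    batch = batch,
    in_channels = c(rep(1L, length(spec$kernels)), spec$m1_filters,
                    spec$m1_filters,
                    rep(spec$m1_filters + 1L, length(spec$kernels)),
                    spec$m2_filters, spec$m2_filters,
                    spec$common_filters[1], spec$common_filters[1],
                    spec$common_filters[2], spec$common_filters[2],
                    spec$flat_dim),
    out_channels = c(rep(spec$m1_filters, length(spec$kernels)),
                     spec$m1_filters, spec$m1_filters + 1L,
                     rep(spec$m2_filters, length(spec$kernels)),
                     spec$m2_filters, spec$common_filters[1],
                     spec$common_filters[1], spec$common_filters[2],
                     spec$common_filters[2], spec$flat_dim, spec$n_classes),
    length = c(rep(L, length(spec$kernels)), L, L,
               rep(L, length(spec$kernels)), L, L, L1, L1, L2, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

kaiming_taps <- function(k, c_in, c_out) {
  sd <- sqrt(2 / (c_in * k))
  lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(c_in * c_out, sd = sd), c_in, c_out)
  })
}

#' Build a CascadeSeed model with Kaiming-initialized weights
#'
#' @param spec A [model_spec()].
#' @param rng_seed Seed for the fan-in-scaled normal initialization.
#' @return An object of class `cascadeseed` (untrained).
#' @export
build_cascadeseed <- function(spec, rng_seed = 1L) {
  if (!inherits(spec, "model_spec")) stop("expected a `model_spec`", call. = FALSE)
  with_seed(rng_seed, {
    mk_mrf <- function(c_in, c_out) {
      W <- lapply(spec$kernels, function(k) kaiming_taps(k, c_in, c_out))
      names(W) <- paste0("c", spec$kernels)
      b <- lapply(spec$kernels, function(k) rep(0, c_out))
      names(b) <- names(W)
      list(W = W, b = b)
    }
    params <- list(
      m1 = mk_mrf(1L, spec$m1_filters),
      m2 = mk_mrf(spec$m1_filters + 1L, spec$m2_filters),
      c3 = list(W = kaiming_taps(3L, spec$m2_filters, spec$common_filters[1]),
                b = rep(0, spec$common_filters[1])),
      c4 = list(W = kaiming_taps(3L, spec$common_filters[1],
                                 spec$common_filters[2]),
                b = rep(0, spec$common_filters[2])),
      head = list(W = matrix(stats::rnorm(spec$flat_dim * spec$n_classes,
                                          sd = sqrt(2 / spec$flat_dim)),
                             spec$flat_dim, spec$n_classes),
                  b = rep(0, spec$n_classes))
    )
    structure(list(spec = spec, params = params, classes = NULL,
                   band_axis = NULL, history = NULL),
              class = "cascadeseed")
  })
}

#' @export
print.cascadeseed <- function(x, ...) {
  cat(sprintf("<cascadeseed> %d bands -> %d classes%s\n",
              x$spec$n_bands, x$spec$n_classes,
              if (is.null(x$history)) " (untrained)" else ""))
  if (!is.null(x$classes)) cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# Full forward pass; returns logits and, when cache = TRUE, every
# intermediate needed for backpropagation.
cascadeseed_forward <- function(params, spec, X, cache = FALSE) {
  n <- nrow(X); L <- spec$n_bands
  A0 <- matrix(as.numeric(t(X)), nrow = 1L)
  e1 <- mrf_eff(params$m1)
  Z1 <- conv_fwd(A0, e1$taps, e1$bias, n, L)
  A1 <- pmax(Z1, 0)
  C1 <- rbind(A1, A0)
  e2 <- mrf_eff(params$m2)
  Z2 <- conv_fwd(C1, e2$taps, e2$bias, n, L)
  A2 <- pmax(Z2, 0)
  Z3 <- conv_fwd(A2, params$c3$W, params$c3$b, n, L)
  A3 <- pmax(Z3, 0)
  pl1 <- maxpool_fwd(A3, n, L)
  L1 <- pl1$L2
  Z4 <- conv_fwd(pl1$out, params$c4$W, params$c4$b, n, L1)
  A4 <- pmax(Z4, 0)
  pl2 <- maxpool_fwd(A4, n, L1)
  L2 <- pl2$L2
  F <- flatten_act(pl2$out, n, L2)
  logits <- F %*% params$head$W + rep(params$head$b, each = n)
  if (!cache) return(list(logits = logits))
  list(logits = logits, n = n, A0 = A0, e1 = e1, Z1 = Z1, C1 = C1, e2 = e2,
       Z2 = Z2, A2 = A2, Z3 = Z3, A3 = A3, pl1 = pl1, Z4 = Z4, A4 = A4,
       pl2 = pl2, F = F)
}

# Backward pass from dlogits; returns parameter gradients and, when
# need_input_grad, the gradient with respect to the input spectra (n x L).
cascadeseed_backward <- function(params, spec, cache, dlogits,
                                 need_param_grads = TRUE,
                                 need_input_grad = FALSE) {
  n <- cache$n; L <- spec$n_bands
  L1 <- cache$pl1$L2; L2 <- cache$pl2$L2
  grads <- list()
  dF <- dlogits %*% t(params$head$W)
  if (need_param_grads) {
    grads$head <- list(W = crossprod(cache$F, dlogits), b = colSums(dlogits))
  }
  dP2 <- unflatten_act(dF, n, L2, spec$common_filters[2])
  dA4 <- maxpool_bwd(dP2, cache$pl2, n, L1)
  dZ4 <- dA4 * (cache$Z4 > 0)
  bk4 <- conv_bwd(dZ4, cache$pl1$out, params$c4$W, n, L1, need_param_grads)
  if (need_param_grads) grads$c4 <- list(W = bk4$dW, b = bk4$db)
  dA3 <- maxpool_bwd(bk4$dA, cache$pl1, n, L)
  dZ3 <- dA3 * (cache$Z3 > 0)
  bk3 <- conv_bwd(dZ3, cache$A2, params$c3$W, n, L, need_param_grads)
  if (need_param_grads) grads$c3 <- list(W = bk3$dW, b = bk3$db)
  dZ2 <- bk3$dA * (cache$Z2 > 0)
  bk2 <- conv_bwd(dZ2, cache$C1, cache$e2$taps, n, L, need_param_grads)
  if (need_param_grads) {
    grads$m2 <- mrf_scatter_grads(params$m2, bk2$dW, bk2$db)
  }
  nf <- spec$m1_filters
  dA1 <- bk2$dA[seq_len(nf), , drop = FALSE]
  dA0_cat <- bk2$dA[nf + 1L, , drop = FALSE]
  dZ1 <- dA1 * (cache$Z1 > 0)
  bk1 <- conv_bwd(dZ1, cache$A0, cache$e1$taps, n, L, need_param_grads)
  if (need_param_grads) {
    grads$m1 <- mrf_scatter_grads(params$m1, bk1$dW, bk1$db)
  }
  out <- list(grads = if (need_param_grads) grads else NULL)
  if (need_input_grad) {
    dA0 <- bk1$dA + dA0_cat
    out$dX <- t(matrix(dA0, nrow = L, ncol = n))
  }
  out
}

#' Numerically stable softmax
#'
#' `P_j = exp(z_j) / sum(exp(z))`, computed max-shifted. For a matrix the
#' transform is applied row-wise.
#'
#' @param z Finite numeric vector of class scores, or a matrix of row
#'   vectors.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    zs <- z - apply(z, 1, max)
    e <- exp(zs)
    return(e / rowSums(e))
  }
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  e <- exp(z - max(z))
  e / sum(e)
}

# --- parameter-tree utilities (Adam) ---------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    stopifnot(length(a) == length(b))
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# --- training ---------------------------------------------------------------

#' Training configuration for CascadeSeed models
#'
#' Defaults mirror the full training protocol (10,000 epochs, learning
#' rate 5e-4, batch 256, Adam, 10% stratified validation carve-out,
#' checkpoint at maximum validation accuracy); pass a smaller `epochs` for
#' desk-scale runs.
#'
#' @param epochs Number of passes over the training partition.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of the training set carved out (stratified)
#'   for validation checkpointing; in (0, 1).
#' @param rng_seed Seed for the validation split and epoch shuffles.
#' @param verbose Print per-epoch progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 10000L, learning_rate = 5e-4,
                         batch_size = 256L, val_fraction = 0.1,
                         rng_seed = 1L, verbose = FALSE) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("`val_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, rng_seed = as.integer(rng_seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a CascadeSeed model
#'
#' Minimizes mean cross-entropy with Adam over minibatches. A stratified
#' `val_fraction` of the samples is carved out for validation; the
#' parameter snapshot with the highest validation accuracy is returned,
#' accuracy ties broken by the lower validation cross-entropy and then by
#' the earlier epoch (small validation sets saturate at accuracy 1 early,
#' so the loss tie-break keeps the better-calibrated snapshot).
#' Deterministic given the configuration seed and the model's
#' initialization seed.
#'
#' @param model An untrained [build_cascadeseed()] model.
#' @param train A `spectrum_set` with labels, or a list `list(x, y)` with a
#'   numeric matrix `x` and label vector `y`.
#' @param cfg A [train_config()].
#' @param label Which label of a `spectrum_set` to fit: `"variety"` or
#'   `"gm"`.
#' @return The trained `cascadeseed` with `classes`, `history` (per-epoch
#'   loss and validation accuracy) and `best_epoch` attached.
#' @export
train_model <- function(model, train, cfg = train_config(),
                        label = c("variety", "gm")) {
  label <- match.arg(label)
  if (inherits(train, "spectrum_set")) {
    x <- train$spectra
    y <- train[[label]]
    if (is.null(y)) stop("training set lacks `", label, "` labels", call. = FALSE)
  } else {
    x <- as.matrix(train$x); y <- train$y
  }
  if (ncol(x) != model$spec$n_bands) {
    stop(sprintf("model expects %d bands, data has %d",
                 model$spec$n_bands, ncol(x)), call. = FALSE)
  }
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L) {
    stop("invalid training set: need at least 2 classes", call. = FALSE)
  }
  if (length(classes) != model$spec$n_classes) {
    stop(sprintf("model has %d output classes but data has %d",
                 model$spec$n_classes, length(classes)), call. = FALSE)
  }
  if (any(table(y) < 2L)) {
    stop("invalid training set: every class needs >= 2 samples", call. = FALSE)
  }
  yi <- match(as.character(y), classes)
  n <- nrow(x)
  spec <- model$spec
  with_seed(cfg$rng_seed, {
    # stratified validation carve-out
    val_idx <- unlist(lapply(seq_along(classes), function(k) {
      ck <- which(yi == k)
      nv <- max(1L, round(cfg$val_fraction * length(ck)))
      sample(ck, nv)
    }))
    tr_idx <- setdiff(seq_len(n), val_idx)
    x_tr <- x[tr_idx, , drop = FALSE]; y_tr <- yi[tr_idx]
    x_val <- x[val_idx, , drop = FALSE]; y_val <- yi[val_idx]
    onehot <- diag(length(classes))
    params <- model$params
    state <- adam_init(params)
    best <- list(acc = -Inf, loss = Inf, params = params, epoch = 0L)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_accuracy = numeric(0), val_loss = numeric(0))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(tr_idx))
      total_loss <- 0
      starts <- seq(1L, length(ord), by = cfg$batch_size)
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        xb <- x_tr[bi, , drop = FALSE]
        fw <- cascadeseed_forward(params, spec, xb, cache = TRUE)
        P <- softmax(fw$logits)
        picked <- P[cbind(seq_along(bi), y_tr[bi])]
        loss <- -mean(log(pmax(picked, 1e-12)))
        if (!is.finite(loss)) {
          stop(sprintf("divergence: non-finite loss at epoch %d", ep),
               call. = FALSE)
        }
        total_loss <- total_loss + loss * length(bi)
        dlogits <- (P - onehot[y_tr[bi], , drop = FALSE]) / length(bi)
        bk <- cascadeseed_backward(params, spec, fw, dlogits)
        st <- adam_step(params, bk$grads, state, cfg$learning_rate)
        params <- st$params; state <- st$state
      }
      val_logits <- cascadeseed_forward(params, spec, x_val)$logits
      val_pred <- max.col(val_logits, ties.method = "first")
      val_acc <- mean(val_pred == y_val)
      Pv <- softmax(val_logits)
      val_loss <- -mean(log(pmax(Pv[cbind(seq_along(y_val), y_val)], 1e-12)))
      history[ep, ] <- list(ep, total_loss / length(tr_idx), val_acc, val_loss)
      # checkpoint: highest validation accuracy; accuracy ties broken by
      # lower validation cross-entropy, then by the earlier epoch
      if (val_acc > best$acc ||
          (val_acc == best$acc && val_loss < best$loss - 1e-12)) {
        best <- list(acc = val_acc, loss = val_loss, params = params,
                     epoch = ep)
      }
      if (cfg$verbose) {
        message(sprintf("epoch %d: loss %.4f, val acc %.4f, val loss %.4f",
                        ep, total_loss / length(tr_idx), val_acc, val_loss))
      }
    }
    model$params <- best$params
    model$classes <- classes
    model$history <- history
    model$best_epoch <- best$epoch
    model$val_accuracy <- best$acc
    model
  })
}

#' Predict with a trained CascadeSeed model
#'
#' @param object A trained `cascadeseed`.
#' @param newdata Numeric matrix of spectra, or a `spectrum_set`.
#' @param type `"class"` (labels), `"prob"` (softmax matrix) or `"logit"`.
#' @param batch Internal forward batch size.
#' @param ... Unused.
#' @return Predicted labels, probabilities or raw scores. Argmax ties break
#'   to the lowest class index.
#' @export
predict.cascadeseed <- function(object, newdata, type = c("class", "prob", "logit"),
                                batch = 512L, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "spectrum_set")) newdata$spectra else as.matrix(newdata)
  if (ncol(x) != object$spec$n_bands) {
    stop(sprintf("model expects %d bands, data has %d",
                 object$spec$n_bands, ncol(x)), call. = FALSE)
  }
  logits <- matrix(0, nrow(x), object$spec$n_classes)
  for (s in seq(1L, nrow(x), by = batch)) {
    ii <- s:min(s + batch - 1L, nrow(x))
    logits[ii, ] <- cascadeseed_forward(object$params, object$spec,
                                        x[ii, , drop = FALSE])$logits
  }
  if (type == "logit") return(logits)
  if (type == "prob") {
    P <- softmax(logits)
    colnames(P) <- object$classes
    return(P)
  }
  idx <- max.col(logits, ties.method = "first")
  if (is.null(object$classes)) idx else object$classes[idx]
}
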