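# Two-phase cascade: a variety classifier (CascadeSeed-1) routes each
# spectrum to a per-variety GM-status classifier (CascadeSeed-2).

#' Assemble a cascade model
#'
#' @param variety_model A trained `cascadeseed` over the variety classes.
#' @param gm_registry Named list mapping each variety name to a trained
#'   binary `cascadeseed` over GM status.
#' @return An object of class `cascade_model`.
#' @export
cascade_model <- function(variety_model, gm_registry) {
  if (!inherits(variety_model, "cascadeseed") || is.null(variety_model$classes)) {
    stop("`variety_model` must be a trained cascadeseed", call. = FALSE)
  }
  if (!is.list(gm_registry) || is.null(names(gm_registry))) {
    stop("`gm_registry` must be a named list of trained models", call. = FALSE)
  }
  structure(list(variety_model = variety_model, gm_registry = gm_registry),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> varieties: %s\n",
              paste(x$variety_model$classes, collapse = ", ")))
  cat(sprintf("  GM models for: %s\n",
              paste(names(x$gm_registry), collapse = ", ")))
  invisible(x)
}

#' Train the full cascade on a labeled spectrum set
#'
#' Phase 1 fits a variety classifier on all samples; phase 2 fits one
#' binary GM-status classifier per variety on that variety's samples.
#' Model initialization and training seeds are derived from `rng_seed`.
#'
#' @param train A `spectrum_set` with both `variety` and `gm` labels.
#' @param cfg A [train_config()]; applied to the variety model (and, when
#'   `gm_cfg` is `NULL`, to the GM models too).
#' @param rng_seed Base seed for weight initialization and split/shuffle.
#' @param gm_cfg Optional [train_config()] for the per-variety GM models;
#'   the subtler GM contrast typically needs more epochs than the variety
#'   phase.
#' @return A `cascade_model`.
#' @export
train_cascade <- function(train, cfg = train_config(), rng_seed = 1L,
                          gm_cfg = NULL) {
  if (is.null(gm_cfg)) gm_cfg <- cfg
  if (is.null(train$variety) || is.null(train$gm)) {
    stop("training set needs both `variety` and `gm` labels", call. = FALSE)
  }
  B <- n_bands(train$band_axis)
  varieties <- sort(unique(train$variety))
  cfg1 <- cfg; cfg1$rng_seed <- rng_seed
  m1 <- build_cascadeseed(model_spec(B, length(varieties)), rng_seed = rng_seed)
  m1 <- train_model(m1, train, cfg1, label = "variety")
  m1$band_axis <- train$band_axis
  registry <- list()
  for (vi in seq_along(varieties)) {
    v <- varieties[vi]
    sub <- subset_samples(train, train$variety == v)
    cfg2 <- gm_cfg; cfg2$rng_seed <- rng_seed + vi
    m2 <- build_cascadeseed(model_spec(B, 2L), rng_seed = rng_seed + vi)
    m2 <- train_model(m2, sub, cfg2, label = "gm")
    m2$band_axis <- train$band_axis
    registry[[v]] <- m2
  }
  cascade_model(m1, registry)
}

#' Two-phase cascade prediction
#'
#' Phase 1 picks the variety by softmax argmax (ties to the lowest class
#' index); the identical spectrum is then routed to that variety's GM
#' model. Confidences are the softmax maxima of each phase.
#'
#' @param cascade A `cascade_model`.
#' @param set A `spectrum_set` (labels optional) or numeric spectra matrix.
#' @return A data frame: `id`, `variety`, `variety_conf`, `gm`, `gm_conf`.
#' @export
cascade_predict <- function(cascade, set) {
  x <- if (inherits(set, "spectrum_set")) set$spectra else as.matrix(set)
  ids <- if (inherits(set, "spectrum_set")) set$sample_id else
    paste0("sample_", seq_len(nrow(x)))
  vp <- predict(cascade$variety_model, x, type = "prob")
  v_idx <- max.col(vp, ties.method = "first")
  variety <- cascade$variety_model$classes[v_idx]
  v_conf <- vp[cbind(seq_len(nrow(vp)), v_idx)]
  missing <- setdiff(unique(variety), names(cascade$gm_registry))
  if (length(missing)) {
    stop(sprintf("missing GM model for predicted variety \"%s\"", missing[1]),
         call. = FALSE)
  }
  gm <- character(nrow(x)); gm_conf <- numeric(nrow(x))
  for (v in unique(variety)) {
    rows <- which(variety == v)
    gp <- predict(cascade$gm_registry[[v]], x[rows, , drop = FALSE],
                  type = "prob")
    g_idx <- max.col(gp, ties.method = "first")
    gm[rows] <- cascade$gm_registry[[v]]$classes[g_idx]
    gm_conf[rows] <- gp[cbind(seq_along(rows), g_idx)]
  }
  data.frame(id = ids, variety = variety, variety_conf = v_conf,
             gm = gm, gm_conf = gm_conf, stringsAsFactors = FALSE)
}

# --- checkpoint serialization (JSON sidecar + flat weight vector) ----------

flatten_params <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, flatten_params), use.names = FALSE))
  as.numeric(p)
}

refill_params <- function(template, values, pos = 1L) {
  if (is.list(template)) {
    out <- template
    for (i in seq_along(template)) {
      r <- refill_params(template[[i]], values, pos)
      out[[i]] <- r$node
      pos <- r$pos
    }
    return(list(node = out, pos = pos))
  }
  k <- length(template)
  node <- template
  node[] <- values[pos:(pos + k - 1L)]
  list(node = node, pos = pos + k)
}

#' Save a trained CascadeSeed model
#'
#' Writes `<path>.json` (architecture spec, classes, band axis, training
#' metadata) and `<path>.weights` (flat weight vector, one value per line).
#'
#' @param model A `cascadeseed`.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
save_cascadeseed <- function(model, path) {
  meta <- list(
    spec = unclass(model$spec),
    classes = model$classes,
    band_axis = if (!is.null(model$band_axis)) {
      list(domain = model$band_axis$domain, values = model$band_axis$values)
    },
    best_epoch = model$best_epoch,
    val_accuracy = model$val_accuracy
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(format(flatten_params(model$params), digits = 17),
             paste0(path, ".weights"))
  invisible(path)
}

#' Load a CascadeSeed model saved by [save_cascadeseed()]
#' @param path Path stem used at save time.
#' @return A `cascadeseed`.
#' @export
load_cascadeseed <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(model_spec, meta$spec[c("n_bands", "n_classes", "m1_filters",
                                          "m2_filters", "common_filters",
                                          "kernels")])
  model <- build_cascadeseed(spec, rng_seed = 0L)
  vals <- as.numeric(readLines(paste0(path, ".weights")))
  model$params <- refill_params(model$params, vals)$node
  model$classes <- meta$classes
  if (!is.null(meta$band_axis)) {
    model$band_axis <- band_axis(meta$band_axis$domain, meta$band_axis$values)
  }
  model$best_epoch <- meta$best_epoch
  model$val_accuracy <- meta$val_accuracy
  model
}
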