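# Preprocessing: raw spectral cubes -> calibrated, segmented, smoothed,
# baseline-corrected, band-trimmed per-seed spectra.

#' Preprocessing configuration
#'
#' Defaults follow the acquisition protocol: segmentation on the 1363 nm
#' reference band with an 11-pixel adaptive-mean block, 8-connected
#' components, 5-band moving average, airPLS with penalty 1 and 15
#' iterations, and per-domain keep intervals (NIR 958-1630 nm, THz
#' 0.3-2.0 THz).
#'
#' @param ref_band_value Reference band center used for segmentation.
#' @param adaptive_block Odd block size (>= 3) of the local-mean threshold.
#' @param adaptive_offset Added to the local mean before the strict `>`
#'   comparison.
#' @param connectivity 4 or 8 neighbour connectivity for components.
#' @param min_component_px Components smaller than this are dropped.
#' @param ma_window Odd moving-average window (>= 1).
#' @param airpls_lambda airPLS smoothness penalty.
#' @param airpls_iters airPLS reweighting iterations.
#' @param keep_interval Named list of `c(lo, hi)` per domain.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(ref_band_value = 1363, adaptive_block = 11L,
                              adaptive_offset = 0, connectivity = 8L,
                              min_component_px = 5L, ma_window = 5L,
                              airpls_lambda = 1, airpls_iters = 15L,
                              keep_interval = list(NIR = c(958, 1630),
                                                   THz = c(0.3, 2.0))) {
  if (adaptive_block %% 2 == 0 || adaptive_block < 3) {
    stop("`adaptive_block` must be odd and >= 3", call. = FALSE)
  }
  if (ma_window %% 2 == 0 || ma_window < 1) {
    stop("`ma_window` must be odd and >= 1", call. = FALSE)
  }
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8", call. = FALSE)
  if (airpls_iters < 1) stop("`airpls_iters` must be >= 1", call. = FALSE)
  for (iv in keep_interval) {
    if (iv[1] >= iv[2]) stop("keep interval must have lo < hi", call. = FALSE)
  }
  structure(list(ref_band_value = ref_band_value,
                 adaptive_block = as.integer(adaptive_block),
                 adaptive_offset = adaptive_offset,
                 connectivity = as.integer(connectivity),
                 min_component_px = as.integer(min_component_px),
                 ma_window = as.integer(ma_window),
                 airpls_lambda = airpls_lambda,
                 airpls_iters = as.integer(airpls_iters),
                 keep_interval = keep_interval),
            class = "preprocess_config")
}

#' Flat-field reflectance calibration
#'
#' `reflectance = (raw - dark) / (white - dark)` elementwise, using the dark
#' (shuttered) and white (reference panel) cubes.
#'
#' @param raw,dark,white `hypercube`s of identical shape.
#' @return A calibrated `hypercube`.
#' @export
calibrate_reflectance <- function(raw, dark, white) {
  for (x in list(raw, dark, white)) {
    if (!inherits(x, "hypercube")) stop("inputs must be hypercubes", call. = FALSE)
  }
  if (!identical(dim(raw$values), dim(dark$values)) ||
      !identical(dim(raw$values), dim(white$values))) {
    stop("raw, dark and white cubes must share a shape", call. = FALSE)
  }
  denom <- white$values - dark$values
  bad <- which(denom == 0)
  if (length(bad)) {
    pos <- arrayInd(bad[1], dim(denom))
    stop(sprintf(
      "degenerate calibration: white == dark at pixel (%d, %d), band %d",
      pos[1], pos[2], pos[3]), call. = FALSE)
  }
  hypercube((raw$values - dark$values) / denom, raw$band_axis)
}

# Exact local box mean with truncated windows at the borders, via an
# integral image. block must be odd.
local_box_mean <- function(img, block) {
  h <- (block - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # padded cumulative sum: S[i+1, j+1] = sum(img[1:i, 1:j])
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  if (nc == 1L) S[-1L, -1L] <- matrix(cumsum(img), ncol = 1L)
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

# Connected-component labeling of a logical mask by breadth-first search in
# raster (row-major) order; connectivity 4 or 8.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L)
    dc <- c(0L, -1L, 1L, 0L)
  }
  next_label <- 0L
  # raster order: row by row, left to right
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || labels[r0, c0] != 0L) next
    next_label <- next_label + 1L
    queue <- matrix(c(r0, c0), ncol = 2L)
    labels[r0, c0] <- next_label
    while (nrow(queue) > 0L) {
      cur <- queue[1L, , drop = FALSE]
      queue <- queue[-1L, , drop = FALSE]
      rr <- cur[1] + dr; cc <- cur[2] + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      rr <- rr[ok]; cc <- cc[ok]
      for (j in seq_along(rr)) {
        if (mask[rr[j], cc[j]] && labels[rr[j], cc[j]] == 0L) {
          labels[rr[j], cc[j]] <- next_label
          queue <- rbind(queue, c(rr[j], cc[j]))
        }
      }
    }
  }
  labels
}

#' Segment seeds with an adaptive-mean threshold
#'
#' A pixel is foreground iff its intensity at the reference band strictly
#' exceeds the local mean over an `adaptive_block` x `adaptive_block`
#' neighbourhood (truncated at image borders) plus `adaptive_offset`.
#' Foreground is labeled into connected components; components smaller than
#' `min_component_px` are dropped and surviving labels renumbered
#' 1..n_seeds in raster order.
#'
#' @param cube A `hypercube`.
#' @param cfg A [preprocess_config()].
#' @return A list of class `seed_mask`: `labels` (integer matrix) and
#'   `n_seeds`.
#' @export
segment_seeds <- function(cube, cfg = preprocess_config()) {
  vals <- cube$band_axis$values
  if (cfg$ref_band_value < min(vals) || cfg$ref_band_value > max(vals)) {
    stop(sprintf("reference band %g outside the axis range [%g, %g]",
                 cfg$ref_band_value, min(vals), max(vals)), call. = FALSE)
  }
  band <- which.min(abs(vals - cfg$ref_band_value))
  img <- cube$values[, , band]
  thr <- local_box_mean(img, cfg$adaptive_block) + cfg$adaptive_offset
  # guard against round-off in the integral image: a pixel must exceed the
  # local mean by more than accumulated floating-point error
  eps <- 1e-9 * max(1, max(abs(img)))
  mask <- img > thr + eps
  labels <- label_components(mask, cfg$connectivity)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels, nbins = max(labels))
    keep <- which(sizes >= cfg$min_component_px)
    relabel <- integer(max(labels))
    relabel[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- relabel[labels[pos]]
  }
  structure(list(labels = labels, n_seeds = max(labels)), class = "seed_mask")
}

#' @export
print.seed_mask <- function(x, ...) {
  cat(sprintf("<seed_mask> %d x %d pixels, %d seeds\n",
              nrow(x$labels), ncol(x$labels), x$n_seeds))
  invisible(x)
}

#' Extract per-seed mean spectra
#'
#' One spectrum per label: the arithmetic mean over that seed's pixels,
#' ordered by label.
#'
#' @param cube A `hypercube`.
#' @param mask A `seed_mask` with the same pixel grid.
#' @return A [spectrum_set()] (empty if the mask has no seeds).
#' @export
extract_mean_spectra <- function(cube, mask) {
  d <- dim(cube$values)
  if (!identical(d[1:2], dim(mask$labels))) {
    stop("cube and mask pixel grids differ", call. = FALSE)
  }
  n <- mask$n_seeds
  B <- d[3]
  if (n == 0L) {
    return(spectrum_set(matrix(numeric(0), 0, B), cube$band_axis,
                        sample_id = character(0)))
  }
  flat <- matrix(cube$values, nrow = d[1] * d[2], ncol = B)
  lab <- as.integer(mask$labels)
  fg <- lab > 0L
  sums <- rowsum(flat[fg, , drop = FALSE], lab[fg])
  counts <- tabulate(lab[fg], nbins = n)
  spectrum_set(sums / counts, cube$band_axis,
               sample_id = paste0("seed_", seq_len(n)))
}

#' Moving-average smoothing
#'
#' Centered boxcar mean per band; at the edges the window is truncated to
#' the available bands (no padding values are invented).
#'
#' @param set A `spectrum_set`.
#' @param window Odd window size, `1 <= window <= n_bands`.
#' @return The smoothed `spectrum_set`.
#' @export
moving_average <- function(set, window = 5L) {
  B <- n_bands(set$band_axis)
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  if (window < 1 || window > B) stop("`window` out of range", call. = FALSE)
  h <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(B), function(j) {
    cols <- max(1L, j - h):min(B, j + h)
    rowMeans(set$spectra[, cols, drop = FALSE])
  }, numeric(nrow(set$spectra)))
  if (nrow(set$spectra) == 1L) sm <- matrix(sm, nrow = 1L)
  spectrum_set(sm, set$band_axis, variety = set$variety, gm = set$gm,
               sample_id = set$sample_id)
}

#' airPLS baseline estimation
#'
#' Adaptive iteratively reweighted penalized least squares: the baseline
#' `z` minimizes `sum(w * (y - z)^2) + lambda * sum(diff(z, d = 2)^2)` with
#' weights re-estimated each iteration — zero where the residual
#' `y - z >= 0` (peak regions are ignored) and growing exponentially with
#' the magnitude of negative residuals, with the endpoints anchored. Exits
#' early when the negative-residual mass falls below 0.1% of the total
#' absolute signal.
#'
#' @param y Numeric spectrum (length >= 3, finite).
#' @param lambda Smoothness penalty (> 0).
#' @param iters Maximum reweighting iterations (>= 1).
#' @return A list with `baseline`, `corrected` (`y - baseline`) and
#'   `iterations` actually run.
#' @export
airpls_baseline <- function(y, lambda = 1, iters = 15L) {
  y <- as.numeric(y)
  m <- length(y)
  if (m < 3L) stop("need at least 3 bands", call. = FALSE)
  if (any(!is.finite(y))) stop("input spectrum must be finite", call. = FALSE)
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (iters < 1) stop("`iters` must be >= 1", call. = FALSE)
  D <- diff(diag(m), differences = 2L)
  DtD <- lambda * crossprod(D)
  w <- rep(1, m)
  total_abs <- sum(abs(y))
  z <- y
  it_done <- 0L
  for (t in seq_len(iters)) {
    A <- DtD
    diag(A) <- diag(A) + w
    z <- solve(A, w * y)
    it_done <- t
    d <- y - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn <= 0.001 * total_abs) break
    w[!neg] <- 0
    w[neg] <- exp(t * abs(d[neg]) / dssn)
    w[1] <- exp(t * max(abs(d[neg])) / dssn)
    w[m] <- w[1]
  }
  list(baseline = z, corrected = y - z, iterations = it_done)
}

#' Apply airPLS baseline correction to every spectrum in a set
#'
#' @param set A `spectrum_set`.
#' @param lambda,iters See [airpls_baseline()].
#' @return The corrected `spectrum_set`.
#' @export
airpls_correct <- function(set, lambda = 1, iters = 15L) {
  corrected <- t(apply(set$spectra, 1, function(y) {
    airpls_baseline(y, lambda, iters)$corrected
  }))
  if (nrow(set$spectra) == 1L) corrected <- matrix(corrected, nrow = 1L)
  spectrum_set(corrected, set$band_axis, variety = set$variety, gm = set$gm,
               sample_id = set$sample_id)
}

#' Trim a spectrum set to a closed band interval
#'
#' Keeps exactly the bands whose center lies in `[interval[1], interval[2]]`
#' (endpoints inclusive) and subsets the band axis accordingly.
#'
#' @param set A `spectrum_set`.
#' @param interval Numeric `c(lo, hi)`.
#' @return The trimmed `spectrum_set`.
#' @export
trim_bands <- function(set, interval) {
  keep <- which(set$band_axis$values >= interval[1] &
                  set$band_axis$values <= interval[2])
  if (length(keep) == 0L) {
    stop("no bands fall inside the requested interval", call. = FALSE)
  }
  subset_bands(set, keep)
}

#' Standard spectral preprocessing chain for a spectrum set
#'
#' Moving-average smoothing, then (for terahertz data, or on request)
#' airPLS baseline correction, then trimming to the domain's keep interval.
#'
#' @param set A `spectrum_set`.
#' @param cfg A [preprocess_config()].
#' @param baseline_correct Apply airPLS; defaults to `TRUE` for THz sets
#'   (the protocol baseline-corrects terahertz spectra only).
#' @return The preprocessed `spectrum_set`.
#' @export
preprocess_spectra <- function(set, cfg = preprocess_config(),
                               baseline_correct = set$band_axis$domain == "THz") {
  out <- moving_average(set, cfg$ma_window)
  if (baseline_correct) {
    out <- airpls_correct(out, cfg$airpls_lambda, cfg$airpls_iters)
  }
  iv <- cfg$keep_interval[[set$band_axis$domain]]
  if (!is.null(iv)) out <- trim_bands(out, iv)
  out
}
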