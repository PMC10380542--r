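# Synthetic spectra and hypercube simulator: labeled fixtures with the
# statistical structure the pipeline assumes (large variety-level shifts,
# small GM-level reductions, smooth drift, additive noise).

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

gauss_peak <- function(x, mu, sigma) exp(-0.5 * ((x - mu) / sigma)^2)

#' Construct a simulation design
#'
#' A design fixes everything the simulator needs: the band axis, variety
#' mean templates (sums of Gaussian peaks plus a smooth baseline), a signed
#' per-band GM offset (zero or negative: non-GM sits at or above GM at every
#' band), the ground-truth discriminative band set, the noise level, the
#' per-cell sample counts and the RNG seed.
#'
#' @param band_axis A [band_axis()].
#' @param varieties Character vector of variety names.
#' @param templates Numeric matrix, `length(varieties) x n_bands`: per-variety
#'   mean spectra.
#' @param gm_offset Numeric vector of length `n_bands`, added to GM samples;
#'   must satisfy `max(abs(gm_offset))` < the minimum pairwise RMS distance
#'   between variety templates (GM shifts are small relative to variety
#'   spacing).
#' @param discriminative_bands Integer indices of the bands that carry the
#'   GM signal (ground truth for selection experiments).
#' @param noise_sd Per-band i.i.d. Gaussian noise standard deviation
#'   (scalar or length `n_bands`).
#' @param drift_sd Amplitude of the per-sample smooth (quadratic) baseline
#'   drift; 0 disables drift.
#' @param class_sizes Integer matrix `length(varieties) x 2` with columns
#'   `non-GM`, `GM`: samples per (variety, GM) cell; all > 0.
#' @param rng_seed Integer seed driving all randomness.
#'
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(band_axis, varieties, templates, gm_offset,
                       discriminative_bands, noise_sd = 0.01, drift_sd = 0,
                       class_sizes, rng_seed = 1L) {
  stopifnot_band_axis(band_axis)
  B <- n_bands(band_axis)
  if (length(varieties) < 1L) stop("`varieties` must be non-empty", call. = FALSE)
  templates <- as.matrix(templates)
  if (nrow(templates) != length(varieties) || ncol(templates) != B) {
    stop("`templates` must be length(varieties) x n_bands", call. = FALSE)
  }
  gm_offset <- as.numeric(gm_offset)
  if (length(gm_offset) == 1L) gm_offset <- rep(gm_offset, B)
  if (length(gm_offset) != B) stop("`gm_offset` must have one value per band", call. = FALSE)
  if (nrow(templates) > 1L) {
    pairs <- utils::combn(nrow(templates), 2)
    d <- apply(pairs, 2, function(p) {
      sqrt(mean((templates[p[1], ] - templates[p[2], ])^2))
    })
    if (max(abs(gm_offset)) >= min(d)) {
      stop("GM offset must be smaller than the variety template spacing",
           call. = FALSE)
    }
  }
  discriminative_bands <- sort(unique(as.integer(discriminative_bands)))
  if (length(discriminative_bands) &&
      (min(discriminative_bands) < 1L || max(discriminative_bands) > B)) {
    stop("`discriminative_bands` out of band range", call. = FALSE)
  }
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, B)
  if (length(noise_sd) != B || any(noise_sd < 0)) {
    stop("`noise_sd` must be nonnegative, scalar or per-band", call. = FALSE)
  }
  class_sizes <- as.matrix(class_sizes)
  if (nrow(class_sizes) != length(varieties) || ncol(class_sizes) != 2L) {
    stop("`class_sizes` must be length(varieties) x 2 (non-GM, GM)", call. = FALSE)
  }
  if (any(class_sizes <= 0) || any(class_sizes != round(class_sizes))) {
    stop("`class_sizes` must be positive integers", call. = FALSE)
  }
  colnames(class_sizes) <- c("non-GM", "GM")
  rownames(class_sizes) <- varieties
  structure(list(band_axis = band_axis, varieties = as.character(varieties),
                 templates = templates, gm_offset = gm_offset,
                 discriminative_bands = discriminative_bands,
                 noise_sd = noise_sd, drift_sd = drift_sd,
                 class_sizes = class_sizes, rng_seed = as.integer(rng_seed)),
            class = "sim_design")
}

# Deterministic terahertz variety templates: narrow absorption lines near
# 0.3, 0.6, 1.0 and 1.25 THz (a line width of ~0.025 THz spans one to two
# bands of the 93-point grid) riding on a broad variety-specific background
# with a rising baseline; chuan345A absorbs strongest around 0.5-0.75 THz.
thz_line_centers <- c(0.32, 0.60, 1.00, 1.25, 1.60)
thz_line_sigma <- 0.025

thz_templates <- function(x) {
  lines <- function(a) {
    rowSums(vapply(seq_along(a), function(i) {
      a[i] * gauss_peak(x, thz_line_centers[i], thz_line_sigma)
    }, numeric(length(x))))
  }
  rbind(
    zheyou5   = 0.30 + 0.10 * x + 0.10 * gauss_peak(x, 0.70, 0.45) +
      lines(c(0.30, 0.22, 0.16, 0.12, 0.08)),
    chuan398A = 0.38 + 0.12 * x + 0.08 * gauss_peak(x, 0.80, 0.50) +
      lines(c(0.27, 0.26, 0.12, 0.15, 0.10)),
    chuan345A = 0.25 + 0.15 * x + 0.12 * gauss_peak(x, 0.65, 0.40) +
      lines(c(0.25, 0.34, 0.20, 0.09, 0.06))
  )
}

# GM-attributable absorbance reduction on the 0.6, 1.0 and 1.25 THz line
# amplitudes; zero elsewhere (non-GM >= GM at every band).
thz_gm_offset <- function(x) {
  -(0.030 * gauss_peak(x, 0.60, thz_line_sigma) +
      0.024 * gauss_peak(x, 1.00, thz_line_sigma) +
      0.020 * gauss_peak(x, 1.25, thz_line_sigma))
}

# Deterministic NIR reflectance templates: broad reflectance plateau with
# water/starch absorption dips near 970, 1200 and 1450 nm, variety-level
# vertical and slope shifts.
nir_templates <- function(x) {
  dips <- function(a) {
    a[1] * gauss_peak(x, 970, 35) + a[2] * gauss_peak(x, 1200, 45) +
      a[3] * gauss_peak(x, 1450, 55)
  }
  u <- (x - min(x)) / diff(range(x))
  rbind(
    zheyou5   = 0.52 + 0.05 * u - dips(c(0.06, 0.10, 0.16)),
    chuan398A = 0.57 + 0.03 * u - dips(c(0.05, 0.12, 0.14)),
    chuan345A = 0.47 + 0.08 * u - dips(c(0.07, 0.08, 0.18))
  )
}

nir_gm_offset <- function(x) {
  -(0.012 * gauss_peak(x, 1200, 40) + 0.010 * gauss_peak(x, 1450, 45))
}

offset_support <- function(gm_offset) {
  which(abs(gm_offset) >= 0.5 * max(abs(gm_offset)))
}

#' Default terahertz simulation design
#'
#' Emulates the terahertz study conditions: 93 bands over 0.3-2.0 THz,
#' three varieties with shared absorption peaks near 0.3/0.6/1.0/1.25 THz,
#' a small negative GM offset on the peak amplitudes, and the per-cell
#' sample counts of the terahertz acquisition protocol
#' (550/554/588/543/578/565, totalling 3378).
#'
#' @param n_per_cell If not `NULL`, overrides every cell count with this
#'   value (used for scaled-down experiments).
#' @param noise_sd,drift_sd,rng_seed See [sim_design()].
#' @return A `sim_design`.
#' @export
sim_design_thz <- function(n_per_cell = NULL, noise_sd = 0.005,
                           drift_sd = 0.02, rng_seed = 1L) {
  axis <- thz_band_axis()
  x <- axis$values
  off <- thz_gm_offset(x)
  sizes <- matrix(c(550L, 554L, 588L, 543L, 578L, 565L),
                  nrow = 3, byrow = TRUE)
  if (!is.null(n_per_cell)) sizes[] <- as.integer(n_per_cell)
  sim_design(axis, c("zheyou5", "chuan398A", "chuan345A"),
             thz_templates(x), off, offset_support(off),
             noise_sd = noise_sd, drift_sd = drift_sd,
             class_sizes = sizes, rng_seed = rng_seed)
}

#' Default NIR simulation design
#'
#' 256 bands over 874-1734 nm, three varieties, smooth reflectance
#' templates with absorption dips, small negative GM offset. Defaults to
#' 800 seeds per (variety, GM) cell.
#'
#' @inheritParams sim_design_thz
#' @return A `sim_design`.
#' @export
sim_design_nir <- function(n_per_cell = 800L, noise_sd = 0.005,
                           drift_sd = 0.02, rng_seed = 1L) {
  axis <- nir_band_axis()
  x <- axis$values
  off <- nir_gm_offset(x)
  sizes <- matrix(as.integer(n_per_cell), nrow = 3, ncol = 2)
  sim_design(axis, c("zheyou5", "chuan398A", "chuan345A"),
             nir_templates(x), off, offset_support(off),
             noise_sd = noise_sd, drift_sd = drift_sd,
             class_sizes = sizes, rng_seed = rng_seed)
}

#' Scaled demonstration design (terahertz axis, 200 seeds per cell)
#'
#' The default condition for desk-scale end-to-end experiments: the
#' terahertz design of [sim_design_thz()] with every cell scaled to 200
#' samples (6 cells, 1200 seeds).
#'
#' @inheritParams sim_design_thz
#' @return A `sim_design`.
#' @export
sim_design_demo <- function(n_per_cell = 200L, rng_seed = 1L) {
  sim_design_thz(n_per_cell = n_per_cell, rng_seed = rng_seed)
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> %s, %d bands, %d varieties, %d samples\n",
              x$band_axis$domain, n_bands(x$band_axis),
              length(x$varieties), sum(x$class_sizes)))
  print(x$class_sizes)
  invisible(x)
}

#' Simulate a labeled spectrum set from a design
#'
#' Each sample is its variety template, plus the GM offset if the sample is
#' GM, plus a per-sample smooth quadratic drift, plus i.i.d. Gaussian band
#' noise. Deterministic given the design's `rng_seed`.
#'
#' @param design A [sim_design()].
#' @return A [spectrum_set()] with `variety` and `gm` labels.
#' @export
simulate_spectrum_set <- function(design) {
  if (!inherits(design, "sim_design")) stop("expected a `sim_design`", call. = FALSE)
  B <- n_bands(design$band_axis)
  u <- seq(-1, 1, length.out = B)
  with_seed(design$rng_seed, {
    blocks <- list(); variety <- character(0); gm <- character(0)
    ids <- character(0)
    for (vi in seq_along(design$varieties)) {
      for (status in c("non-GM", "GM")) {
        n <- design$class_sizes[vi, status]
        mean_vec <- design$templates[vi, ]
        if (status == "GM") mean_vec <- mean_vec + design$gm_offset
        block <- matrix(mean_vec, nrow = n, ncol = B, byrow = TRUE)
        if (design$drift_sd > 0) {
          coef <- matrix(stats::rnorm(3 * n), nrow = n)
          drift <- design$drift_sd *
            (coef[, 1] + coef[, 2] %o% u + coef[, 3] %o% (u^2 - 1 / 3))
          block <- block + drift
        }
        if (any(design$noise_sd > 0)) {
          noise <- matrix(stats::rnorm(n * B), nrow = n, ncol = B)
          block <- block + sweep(noise, 2, design$noise_sd, `*`)
        }
        blocks[[length(blocks) + 1L]] <- block
        variety <- c(variety, rep(design$varieties[vi], n))
        gm <- c(gm, rep(status, n))
        ids <- c(ids, sprintf("%s_%s_%04d", design$varieties[vi],
                              gsub("-", "", status), seq_len(n)))
      }
    }
    spectrum_set(do.call(rbind, blocks), design$band_axis,
                 variety = variety, gm = gm, sample_id = ids)
  })
}

#' Simulate a hyperspectral cube of scattered seeds
#'
#' Places `n_seeds` axis-aligned elliptical seed footprints with jittered
#' radii on a near-zero background, fills each footprint with an assigned
#' spectrum from `seed_spectra` plus optional voxel noise, and returns both
#' the cube and the exact ground-truth label image for segmentation scoring.
#'
#' @param n_seeds Number of seeds to place (>= 0).
#' @param cube_shape Integer vector `c(rows, cols)`.
#' @param seed_spectra A [spectrum_set()]; rows are recycled over seeds.
#' @param rng_seed Integer seed.
#' @param noise_sd Voxel-level Gaussian noise sd (0 = noiseless).
#' @param background Background intensity (default 0).
#' @param max_tries Placement retries per seed before failing.
#'
#' @return A list with elements `cube` (a [hypercube()]), `labels` (integer
#'   matrix, 0 = background, k = seed k), and `assignment` (data frame
#'   mapping label to the source spectrum row and id).
#' @export
simulate_hypercube <- function(n_seeds, cube_shape, seed_spectra, rng_seed = 1L,
                               noise_sd = 0, background = 0, max_tries = 200L) {
  if (n_seeds < 0) stop("`n_seeds` must be >= 0", call. = FALSE)
  rows <- cube_shape[1]; cols <- cube_shape[2]
  if (n_seeds > 0 && (rows < 14 || cols < 16)) {
    stop("cube too small to place elliptical seed footprints", call. = FALSE)
  }
  B <- n_bands(seed_spectra$band_axis)
  with_seed(rng_seed, {
    labels <- matrix(0L, rows, cols)
    cube <- array(background, dim = c(rows, cols, B))
    if (noise_sd > 0) {
      cube <- cube + array(stats::rnorm(rows * cols * B, sd = noise_sd),
                           dim = c(rows, cols, B))
    }
    placed <- data.frame(cr = numeric(0), cc = numeric(0),
                         rr = numeric(0), rc = numeric(0))
    if (n_seeds > 0) {
      for (k in seq_len(n_seeds)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          rr <- stats::runif(1, 3, 4.5)
          rc <- stats::runif(1, 4, 5.5)
          cr <- stats::runif(1, rr + 2, rows - rr - 1)
          cc <- stats::runif(1, rc + 2, cols - rc - 1)
          if (nrow(placed) == 0 ||
              all((placed$cr - cr)^2 / (placed$rr + rr + 2)^2 +
                    (placed$cc - cc)^2 / (placed$rc + rc + 2)^2 > 1)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop(structure(class = c("placement_failure", "error", "condition"),
                         list(message = sprintf(
                           "could not place seed %d without overlap after %d tries",
                           k, max_tries), call = NULL)))
        }
        placed[k, ] <- c(cr, cc, rr, rc)
        rge <- seq(max(1L, floor(cr - rr)), min(rows, ceiling(cr + rr)))
        cge <- seq(max(1L, floor(cc - rc)), min(cols, ceiling(cc + rc)))
        for (r in rge) for (cl in cge) {
          if (((r - cr) / rr)^2 + ((cl - cc) / rc)^2 <= 1) labels[r, cl] <- k
        }
      }
      assign_row <- rep_len(seq_len(n_samples(seed_spectra)), n_seeds)
      for (k in seq_len(n_seeds)) {
        px <- which(labels == k, arr.ind = TRUE)
        spec <- seed_spectra$spectra[assign_row[k], ]
        for (j in seq_len(nrow(px))) {
          voxel <- spec
          if (noise_sd > 0) voxel <- voxel + stats::rnorm(B, sd = noise_sd)
          cube[px[j, 1], px[j, 2], ] <- voxel
        }
      }
      assignment <- data.frame(label = seq_len(n_seeds),
                               sample_row = assign_row,
                               sample_id = seed_spectra$sample_id[assign_row],
                               stringsAsFactors = FALSE)
    } else {
      assignment <- data.frame(label = integer(0), sample_row = integer(0),
                               sample_id = character(0))
    }
    list(cube = hypercube(cube, seed_spectra$band_axis),
         labels = labels, assignment = assignment)
  })
}
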