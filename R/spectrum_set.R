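#' Construct a set of per-seed spectra
#'
#' The universal currency between pipeline stages: a numeric matrix with one
#' row per seed and one column per band, together with the band axis and
#' (optionally) variety and GM-status labels.
#'
#' @param spectra Numeric matrix, `n_samples x n_bands`.
#' @param band_axis A [band_axis()] whose length equals `ncol(spectra)`.
#' @param variety Optional character/factor vector of variety labels.
#' @param gm Optional character/factor vector of GM status
#'   (`"GM"` / `"non-GM"`).
#' @param sample_id Optional character vector of unique sample identifiers;
#'   defaults to `seed_1 ... seed_n`.
#'
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, band_axis, variety = NULL, gm = NULL,
                         sample_id = NULL) {
  stopifnot_band_axis(band_axis)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  n <- nrow(spectra)
  if (ncol(spectra) != n_bands(band_axis)) {
    stop(sprintf("spectra have %d columns but the band axis has %d bands",
                 ncol(spectra), n_bands(band_axis)), call. = FALSE)
  }
  check_label <- function(lab, name) {
    if (is.null(lab)) return(NULL)
    lab <- as.character(lab)
    if (length(lab) != n) {
      stop(sprintf("`%s` has length %d but there are %d spectra",
                   name, length(lab), n), call. = FALSE)
    }
    lab
  }
  variety <- check_label(variety, "variety")
  gm <- check_label(gm, "gm")
  if (!is.null(gm) && !all(gm %in% c("GM", "non-GM"))) {
    stop("`gm` labels must be \"GM\" or \"non-GM\"", call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- if (n > 0) paste0("seed_", seq_len(n)) else character(0)
  }
  sample_id <- check_label(sample_id, "sample_id")
  structure(list(spectra = spectra, band_axis = band_axis,
                 variety = variety, gm = gm, sample_id = sample_id),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d bands (%s)\n",
              nrow(x$spectra), n_bands(x$band_axis), x$band_axis$domain))
  if (!is.null(x$variety)) {
    cat("  varieties:", paste(names(table(x$variety)), table(x$variety),
                              sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$gm)) {
    cat("  GM status:", paste(names(table(x$gm)), table(x$gm),
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectrum_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(set) nrow(set$spectra)

#' Subset a spectrum set by sample index
#' @param set A `spectrum_set`.
#' @param idx Integer or logical row index.
#' @return A `spectrum_set` with the selected samples.
#' @export
subset_samples <- function(set, idx) {
  spectrum_set(set$spectra[idx, , drop = FALSE], set$band_axis,
               variety = if (!is.null(set$variety)) set$variety[idx],
               gm = if (!is.null(set$gm)) set$gm[idx],
               sample_id = set$sample_id[idx])
}

#' Subset a spectrum set by band index
#' @param set A `spectrum_set`.
#' @param bands Integer vector of band indices to keep (in axis order).
#' @return A `spectrum_set` restricted to those bands.
#' @export
subset_bands <- function(set, bands) {
  bands <- sort(unique(as.integer(bands)))
  if (any(bands < 1L | bands > n_bands(set$band_axis))) {
    stop("band indices out of range", call. = FALSE)
  }
  if (length(bands) < 2L) stop("need at least 2 bands", call. = FALSE)
  spectrum_set(set$spectra[, bands, drop = FALSE],
               band_axis(set$band_axis$domain, set$band_axis$values[bands]),
               variety = set$variety, gm = set$gm, sample_id = set$sample_id)
}

#' Write a spectrum set to CSV
#'
#' Columns: `id`, `variety`, `gm`, then one column per band named by its
#' center value (e.g. `nm_958.4` or `THz_0.3`).
#'
#' @param set A `spectrum_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(set, path) {
  unit <- band_unit(set$band_axis)
  bn <- paste0(unit, "_", format(set$band_axis$values, trim = TRUE,
                                 digits = 10, scientific = FALSE))
  df <- data.frame(
    id = set$sample_id,
    variety = if (is.null(set$variety)) NA_character_ else set$variety,
    gm = if (is.null(set$gm)) NA_character_ else set$gm,
    stringsAsFactors = FALSE
  )
  mat <- as.data.frame(set$spectra)
  names(mat) <- bn
  utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum set from CSV
#'
#' Inverse of [write_spectrum_csv()]: expects `id`, `variety`, `gm`
#' followed by band columns named `<unit>_<center>`.
#'
#' @param path CSV path.
#' @return A `spectrum_set`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  band_cols <- grep("^(nm|THz)_", names(df))
  if (length(band_cols) < 2L) stop("no band columns found in ", path, call. = FALSE)
  unit <- sub("_.*$", "", names(df)[band_cols[1]])
  centers <- as.numeric(sub("^(nm|THz)_", "", names(df)[band_cols]))
  axis <- band_axis(if (unit == "nm") "NIR" else "THz", centers)
  variety <- df$variety
  gm <- df$gm
  if (all(is.na(variety))) variety <- NULL
  if (all(is.na(gm))) gm <- NULL
  spectrum_set(as.matrix(df[, band_cols, drop = FALSE]), axis,
               variety = variety, gm = gm, sample_id = as.character(df$id))
}
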