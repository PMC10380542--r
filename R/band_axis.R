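#' Construct a spectral band axis
#'
#' A band axis records the centers of the spectral bands of an instrument,
#' either near-infrared wavelengths in nanometres or terahertz frequencies
#' in THz. Band centers form a uniform inclusive grid from `lo` to `hi`.
#'
#' @param domain `"NIR"` (wavelength, nm) or `"THz"` (frequency, THz).
#' @param n_bands Number of bands (>= 2).
#' @param lo,hi First and last band center (`lo < hi`, both positive).
#'
#' @return An object of class `band_axis`: a list with elements `domain`
#'   and `values` (strictly increasing numeric vector of band centers).
#'
#' @examples
#' make_band_axis("NIR", 256, 874, 1734)  # NIR hyperspectral camera grid
#' make_band_axis("THz", 93, 0.3, 2.0)    # terahertz time-domain grid
#' @export
make_band_axis <- function(domain = c("NIR", "THz"), n_bands, lo, hi) {
  domain <- match.arg(domain)
  if (!is.numeric(n_bands) || length(n_bands) != 1L || n_bands < 2 ||
      n_bands != round(n_bands)) {
    stop("`n_bands` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("`lo` must be < `hi` and both finite", call. = FALSE)
  }
  if (lo <= 0) stop("band centers must be positive", call. = FALSE)
  band_axis(domain, seq(lo, hi, length.out = n_bands))
}

#' @rdname make_band_axis
#' @param values Strictly increasing vector of band centers (used by the
#'   lower-level constructor, e.g. when subsetting an existing axis).
#' @export
band_axis <- function(domain = c("NIR", "THz"), values) {
  domain <- match.arg(domain)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a band axis needs at least 2 bands", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("band centers must be finite and positive", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("band centers must be strictly increasing", call. = FALSE)
  }
  structure(list(domain = domain, values = values), class = "band_axis")
}

#' Default NIR camera axis: 256 bands, 874-1734 nm
#' @return A `band_axis`.
#' @export
nir_band_axis <- function() make_band_axis("NIR", 256L, 874, 1734)

#' Default terahertz axis: 93 bands, 0.3-2.0 THz
#' @return A `band_axis`.
#' @export
thz_band_axis <- function() make_band_axis("THz", 93L, 0.3, 2.0)

#' @export
print.band_axis <- function(x, ...) {
  unit <- if (x$domain == "NIR") "nm" else "THz"
  cat(sprintf("<band_axis> %s: %d bands, %.4g-%.4g %s\n",
              x$domain, length(x$values), min(x$values), max(x$values), unit))
  invisible(x)
}

#' @export
length.band_axis <- function(x) length(x$values)

n_bands <- function(axis) length(axis$values)

band_unit <- function(axis) if (axis$domain == "NIR") "nm" else "THz"

stopifnot_band_axis <- function(x) {
  if (!inherits(x, "band_axis")) stop("expected a `band_axis`", call. = FALSE)
  invisible(x)
}

axes_identical <- function(a, b, tol = 1e-9) {
  a$domain == b$domain && length(a$values) == length(b$values) &&
    all(abs(a$values - b$values) < tol)
}
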