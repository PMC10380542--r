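#' Construct a hyperspectral cube
#'
#' A 3-D spectral image: `rows x cols x n_bands`, with the spectral axis
#' described by a [band_axis()].
#'
#' @param values Numeric array `rows x cols x n_bands`.
#' @param band_axis A `band_axis` of length `dim(values)[3]`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, band_axis) {
  stopifnot_band_axis(band_axis)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  }
  if (dim(values)[3] != n_bands(band_axis)) {
    stop(sprintf("cube has %d bands but the axis has %d",
                 dim(values)[3], n_bands(band_axis)), call. = FALSE)
  }
  if (any(!is.finite(values))) stop("cube values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, band_axis = band_axis), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%s)\n",
              d[1], d[2], d[3], x$band_axis$domain))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Write a hypercube as an ENVI band-sequential image
#'
#' Writes `<path>` (raw float32, band-sequential, little-endian) and
#' `<path>.hdr` (plain-text ENVI header carrying the band centers).
#'
#' @param cube A `hypercube`.
#' @param path Output path for the binary image (header gets `.hdr` appended).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  d <- dim(cube$values)
  # BSQ voxel order: samples (cols) fastest, then lines (rows), then bands
  v <- aperm(cube$values, c(2, 1, 3))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  unit <- if (cube$band_axis$domain == "NIR") "Nanometers" else "THz"
  hdr <- c(
    "ENVI",
    "description = {seedcascade spectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("wavelength units = %s", unit),
    paste0("wavelength = {", paste(format(cube$band_axis$values, trim = TRUE,
                                          digits = 10, scientific = FALSE),
                                   collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read an ENVI band-sequential image written by [write_envi()]
#'
#' Supports the subset of ENVI headers this package writes: BSQ interleave,
#' data type 4 (float32) or 5 (float64), byte order 0.
#'
#' @param path Path to the binary image; the header is `<path>.hdr`.
#' @param domain Band-axis domain, `"NIR"` or `"THz"`; if `NULL`, inferred
#'   from the header's wavelength units.
#' @return A `hypercube`.
#' @export
read_envi <- function(path, domain = NULL) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path, call. = FALSE)
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_field <- function(name) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^", name, "\\s*=\\s*[^\n{]+"),
                                 txt, perl = TRUE))
    if (length(m) == 0) return(NULL)
    trimws(sub(".*=", "", m))
  }
  samples <- as.integer(get_field("samples"))
  nlines <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  dtype <- as.integer(get_field("data type"))
  interleave <- tolower(get_field("interleave"))
  if (!identical(interleave, "bsq")) {
    stop("only BSQ interleave is supported (got ", interleave, ")", call. = FALSE)
  }
  if (!dtype %in% c(4L, 5L)) stop("unsupported ENVI data type ", dtype, call. = FALSE)
  size <- if (dtype == 4L) 4L else 8L
  wl <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  if (length(wl) == 0) stop("header lacks a wavelength block", call. = FALSE)
  centers <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl), ",")[[1]])
  if (is.null(domain)) {
    units <- get_field("wavelength units")
    domain <- if (!is.null(units) && grepl("thz", units, ignore.case = TRUE)) "THz" else "NIR"
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = samples * nlines * bands, size = size,
               endian = "little")
  arr <- aperm(array(v, dim = c(samples, nlines, bands)), c(2, 1, 3))
  hypercube(arr, band_axis(domain, centers))
}

#' Write a seed label image as CSV
#'
#' Plain-text export of an integer label matrix (0 = background), one CSV
#' row per image row.
#'
#' @param labels Integer matrix of seed labels.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_csv <- function(labels, path) {
  utils::write.table(labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a seed label image written by [write_label_csv()]
#' @param path CSV path.
#' @return Integer label matrix.
#' @export
read_label_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
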