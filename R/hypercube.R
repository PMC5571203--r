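#' Construct a hypercube
#'
#' A hypercube is a 3-D reflectance (or raw-count) block with axes
#' \code{[line, sample, band]} plus a strictly increasing wavelength axis in
#' nanometres.  This is the in-memory counterpart of an ENVI/BIL file pair.
#'
#' @param values numeric 3-D array, dimensions \code{lines x samples x bands}.
#' @param wavelengths numeric vector of band-centre wavelengths (nm),
#'   strictly increasing, length equal to \code{dim(values)[3]}.
#' @param dtype on-disk storage type: \code{"float32"} for reflectance or
#'   \code{"uint16"} for raw counts.
#' @return An object of class \code{"hypercube"}: a list with elements
#'   \code{values}, \code{wavelengths}, \code{interleave} (always
#'   \code{"bil"}) and \code{dtype}.
#' @examples
#' cube <- hypercube(array(0.5, c(4, 3, 2)), wavelengths = c(500, 600))
#' dim(cube$values)
#' @export
hypercube <- function(values, wavelengths, dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  pm_check(is.array(values) && length(dim(values)) == 3L,
           "values must be a 3-D array [line, sample, band]")
  pm_check(is.numeric(wavelengths) &&
             length(wavelengths) == dim(values)[3L],
           "wavelengths length must equal the band count")
  pm_check(all(is.finite(wavelengths)) && all(diff(wavelengths) > 0),
           "wavelengths must be finite and strictly increasing")
  pm_check(all(is.finite(values)), "cube values must be finite")
  structure(list(values = values,
                 wavelengths = as.numeric(wavelengths),
                 interleave = "bil",
                 dtype = dtype),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands (%s, BIL)\n",
              d[1L], d[2L], d[3L], x$dtype))
  cat(sprintf("  wavelengths: %.1f .. %.1f nm\n",
              x$wavelengths[1L], x$wavelengths[length(x$wavelengths)]))
  invisible(x)
}

#' Linear wavelength axis
#'
#' Builds the evenly spaced band-centre axis of a spectrograph covering
#' \code{[start_nm, end_nm]} inclusive: lambda_i = start + i (end-start)/(n-1).
#'
#' @param start_nm,end_nm range endpoints in nm, \code{end_nm > start_nm}.
#' @param n_bands number of bands (>= 2).
#' @return Numeric vector of length \code{n_bands}.
#' @examples
#' band_wavelengths(380, 1030, 512)[c(1, 512)]
#' @export
band_wavelengths <- function(start_nm, end_nm, n_bands) {
  pm_check(is_scalar_number(start_nm) && is_scalar_number(end_nm) &&
             end_nm > start_nm, "end_nm must exceed start_nm")
  pm_check(is_scalar_number(n_bands) && n_bands >= 2 &&
             n_bands == round(n_bands), "n_bands must be an integer >= 2")
  seq(start_nm, end_nm, length.out = as.integer(n_bands))
}

envi_data_type <- function(dtype) switch(dtype, float32 = 4L, uint16 = 12L)
envi_bytes <- function(dtype) switch(dtype, float32 = 4L, uint16 = 2L)

#' Write a hypercube as ENVI header + BIL binary
#'
#' Emits \code{<path>} (flat binary, band-interleaved-by-line, little-endian)
#' and \code{<path>.hdr} (ASCII header with samples/lines/bands/interleave/
#' data type/byte order/wavelength).  Data type 4 (32-bit float) is used for
#' reflectance cubes and 12 (unsigned 16-bit) for raw cubes.  Float values
#' are quantized to single precision on write, so a written-then-read cube
#' round-trips bit-identically.
#'
#' @param cube a [hypercube()].
#' @param path output binary path; the header is written at \code{<path>.hdr}.
#' @return \code{path}, invisibly.
#' @seealso [read_envi()]
#' @export
write_envi <- function(cube, path) {
  pm_check(inherits(cube, "hypercube"), "cube must be a hypercube")
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", envi_data_type(cube$dtype)),
    "interleave = bil",
    "byte order = 0",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, digits = 15, trim = TRUE),
                 collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  # BIL: per line, band-major rows of samples -> aperm to [sample, band, line]
  v <- aperm(cube$values, c(2L, 1L, 3L))          # [sample, line, band]
  v <- aperm(v, c(1L, 3L, 2L))                    # [sample, band, line]
  con <- file(path, "wb")
  on.exit(close(con))
  if (cube$dtype == "float32") {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  } else {
    iv <- as.integer(round(v))
    pm_check(all(iv >= 0 & iv <= 65535), "uint16 values must be in [0, 65535]")
    writeBin(as.integer(ifelse(iv > 32767L, iv - 65536L, iv)), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  pm_check(file.exists(hdr_path), sprintf("header not found: %s", hdr_path),
           class = "corrupt_file")
  lines <- readLines(hdr_path, warn = FALSE)
  joined <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in lines) {
    if (open) {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { joined <- c(joined, buf); open <- FALSE }
    } else if (grepl("\\{", ln) && !grepl("\\}", ln)) {
      buf <- ln; open <- TRUE
    } else joined <- c(joined, ln)
  }
  kv <- joined[grepl("=", joined)]
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  stats::setNames(as.list(vals), tolower(keys))
}

#' Read an ENVI/BIL hypercube
#'
#' Parses \code{<path>.hdr} and the flat binary at \code{path}.  Only the
#' BIL interleave and data types 4 (float32) / 12 (uint16) are supported;
#' other interleaves raise an \code{unsupported_format} error and a binary
#' whose size disagrees with the header raises \code{corrupt_file}.
#'
#' @param path binary path written by [write_envi()].
#' @return A [hypercube()].
#' @export
read_envi <- function(path) {
  h <- parse_envi_header(paste0(path, ".hdr"))
  need <- c("samples", "lines", "bands", "interleave", "data type")
  pm_check(all(need %in% names(h)),
           "ENVI header missing required keys", class = "corrupt_file")
  interleave <- tolower(h[["interleave"]])
  if (interleave != "bil")
    pm_stop(sprintf("unsupported interleave '%s' (only bil)", interleave),
            "unsupported_format")
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  dt <- as.integer(h[["data type"]])
  dtype <- if (dt == 4L) "float32" else if (dt == 12L) "uint16" else
    pm_stop(sprintf("unsupported ENVI data type %d", dt), "unsupported_format")
  nbytes <- envi_bytes(dtype)
  expected <- as.numeric(nl) * ns * nb * nbytes
  pm_check(file.exists(path), sprintf("binary not found: %s", path),
           class = "corrupt_file")
  actual <- file.info(path)$size
  if (actual != expected)
    pm_stop(sprintf("binary size %d does not match header (%d expected)",
                    actual, expected), "corrupt_file")
  con <- file(path, "rb")
  on.exit(close(con))
  n <- nl * ns * nb
  v <- if (dtype == "float32") {
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  }
  arr <- array(v, dim = c(ns, nb, nl))     # [sample, band, line]
  arr <- aperm(arr, c(3L, 1L, 2L))         # [line, sample, band]
  wl <- if ("wavelength" %in% names(h)) {
    s <- gsub("[{}]", "", h[["wavelength"]])
    as.numeric(strsplit(s, ",")[[1L]])
  } else seq_len(nb)
  hypercube(arr, wl, dtype = dtype)
}

#' White/dark reflectance correction
#'
#' Converts raw counts to relative reflectance per element:
#' \deqn{R = (raw - dark) / (white - dark).}
#' The white and dark references may be per-band scalars (vectors of length
#' \code{bands}, the default acquisition protocol) or full arrays matching
#' the cube.  Values above 1 (specular pixels) are not clipped.
#'
#' @param raw a [hypercube()] of raw counts.
#' @param white,dark reference frames: numeric vectors of length
#'   \code{bands}, or arrays with the cube's dimensions.
#' @return A float32 [hypercube()] of reflectance.
#' @export
reflectance_correct <- function(raw, white, dark) {
  pm_check(inherits(raw, "hypercube"), "raw must be a hypercube")
  d <- dim(raw$values)
  expand <- function(x, what) {
    if (is.null(dim(x)) && length(x) == d[3L]) {
      aperm(array(rep(x, each = d[1L] * d[2L]), dim = d), c(1L, 2L, 3L))
    } else if (is.array(x) && identical(dim(x), d)) {
      x
    } else pm_stop(sprintf(
      "%s reference must be a per-band vector or an array matching the cube",
      what), "invalid_argument")
  }
  w <- expand(white, "white"); k <- expand(dark, "dark")
  denom <- w - k
  if (any(denom <= 0))
    pm_stop("white reference must exceed dark at every used element",
            "degenerate_reference")
  hypercube((raw$values - k) / denom, raw$wavelengths, dtype = "float32")
}
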