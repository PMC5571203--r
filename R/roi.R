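#' Threshold-based ROI segmentation
#'
#' Separates flesh pixels from background by thresholding the band nearest
#' to \code{band_nm} and keeping the largest 4-connected component.
#' Automates the manual ROI drawing of an interactive workstation for
#' synthetic and batch data.
#'
#' @param cube a [hypercube()].
#' @param band_nm wavelength (nm) of the band to threshold; must lie within
#'   the cube's wavelength range.  Defaults to the band with the largest
#'   reflectance spread (highest contrast).
#' @param threshold reflectance threshold; pixels strictly above it are
#'   candidate flesh.
#' @return Logical matrix (class \code{"roi_mask"} attribute-free) matching
#'   the cube's spatial axes.
#' @export
threshold_segment <- function(cube, band_nm = NULL, threshold = 0.1) {
  pm_check(inherits(cube, "hypercube"), "cube must be a hypercube")
  wl <- cube$wavelengths
  if (is.null(band_nm)) {
    spread <- apply(cube$values, 3L, function(p) diff(range(p)))
    j <- which.max(spread)
  } else {
    pm_check(band_nm >= min(wl) && band_nm <= max(wl),
             "band_nm outside the cube's wavelength range")
    j <- which.min(abs(wl - band_nm))
  }
  plane <- cube$values[, , j]
  cand <- plane > threshold
  if (!any(cand)) pm_stop("threshold leaves no pixels", "empty_roi")
  lab <- EBImage::bwlabel(cand * 1)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  mask <- lab == keep
  storage.mode(mask) <- "logical"
  mask
}

#' Extract per-pixel spectra under a mask
#'
#' One row per masked pixel in deterministic raster-scan (row-major) order:
#' pixels are visited line by line, left to right.
#'
#' @param cube a [hypercube()].
#' @param mask logical matrix matching the cube's spatial axes, non-empty.
#' @return Numeric matrix \code{n_pixels x n_bands}.
#' @export
extract_pixel_spectra <- function(cube, mask) {
  pm_check(inherits(cube, "hypercube"), "cube must be a hypercube")
  d <- dim(cube$values)
  if (!identical(dim(mask), d[1:2]))
    pm_stop("mask shape does not match cube", "invalid_argument")
  if (!any(mask)) pm_stop("empty ROI", "empty_roi")
  # raster order: rows (lines) outer, columns (samples) inner
  ord <- which(t(mask))                       # row-major scan positions
  flat <- matrix(cube$values, d[1L] * d[2L], d[3L])  # column-major pixels
  rows <- ((ord - 1L) %% d[2L]) * d[1L] + ((ord - 1L) %/% d[2L]) + 1L
  flat[rows, , drop = FALSE]
}

#' Slice-level mean spectrum
#'
#' Per-band arithmetic mean over the masked pixels: the characteristic
#' spectrum of a slice sample.
#'
#' @inheritParams extract_pixel_spectra
#' @return Numeric vector of length \code{n_bands}.
#' @export
mean_spectrum <- function(cube, mask) {
  colMeans(extract_pixel_spectra(cube, mask))
}

# Absorbance transform used throughout calibration: log10(1/R), with a small
# positive floor so noisy near-zero reflectance cannot produce infinities.
to_absorbance <- function(R, floor = 1e-6) -log10(pmax(R, floor))

#' Build a calibration table from cubes, masks and reference values
#'
#' Row i of \code{X} is the slice-level characteristic spectrum of slice i;
#' the reference contents (mg/g) are carried alongside.  When a slice was
#' imaged more than once (e.g. front and back faces), pass a list of cubes
#' for that slice: their mean spectra are averaged with equal weight.
#'
#' By default spectra are converted pixel-wise to absorbance log10(1/R)
#' before spatial averaging, which preserves the linearity between the mean
#' spectrum and the mean concentration of a heterogeneous slice
#' (Beer-Lambert); set \code{scale = "reflectance"} to average raw
#' reflectance instead.
#'
#' @param cubes list of [hypercube()]s, or list of lists of cubes (multiple
#'   faces per slice).  All cubes must share one wavelength axis.
#' @param masks list of logical masks parallel to \code{cubes}.
#' @param references data.frame with columns \code{sample_id},
#'   \code{protopectin}, \code{water_soluble}, \code{total} (mg/g), one row
#'   per slice.
#' @param scale \code{"absorbance"} (default) or \code{"reflectance"}.
#' @return An object of class \code{"calibration_table"}: list with
#'   \code{X} (n x bands matrix), \code{y} (data.frame of the three
#'   reference columns), \code{wavelengths}, \code{sample_ids},
#'   \code{scale}.
#' @export
build_calibration_table <- function(cubes, masks, references,
                                    scale = c("absorbance", "reflectance")) {
  scale <- match.arg(scale)
  pm_check(is.list(cubes) && length(cubes) >= 1, "cubes must be a list")
  pm_check(length(masks) == length(cubes),
           "one mask (list entry) per slice required")
  need <- c("sample_id", "protopectin", "water_soluble", "total")
  pm_check(is.data.frame(references) && all(need %in% names(references)),
           "references needs sample_id/protopectin/water_soluble/total")
  pm_check(nrow(references) == length(cubes),
           "one reference row per slice required")
  pm_check(!anyNA(references[need]), "references contain missing values")
  wl <- NULL
  slice_mean <- function(cube, mask) {
    px <- extract_pixel_spectra(cube, mask)
    if (scale == "absorbance") px <- to_absorbance(px)
    colMeans(px)
  }
  X <- matrix(NA_real_, length(cubes), 0L)
  rows <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    ci <- cubes[[i]]
    faces <- if (inherits(ci, "hypercube")) list(ci) else ci
    mi <- masks[[i]]
    mfaces <- if (is.list(mi)) mi else rep(list(mi), length(faces))
    specs <- mapply(function(f, m) {
      if (is.null(wl)) wl <<- f$wavelengths
      else if (!isTRUE(all.equal(wl, f$wavelengths, tolerance = 0)) &&
               !identical(wl, f$wavelengths))
        pm_stop("cubes have mismatched wavelength axes", "incompatible_sets")
      slice_mean(f, m)
    }, faces, mfaces, SIMPLIFY = FALSE)
    rows[[i]] <- Reduce(`+`, specs) / length(specs)
  }
  X <- do.call(rbind, rows)
  colnames(X) <- NULL
  structure(list(X = X,
                 y = references[c("protopectin", "water_soluble", "total")],
                 wavelengths = wl,
                 sample_ids = as.character(references$sample_id),
                 scale = scale),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table> %d slices x %d bands (%s scale)\n",
              nrow(x$X), ncol(x$X), x$scale))
  invisible(x)
}

#' Write / read a calibration table as CSV
#'
#' Layout: \code{sample_id}, the three reference columns, then one column
#' per wavelength (named \code{wl_<nm>}).
#'
#' @param table a [build_calibration_table()] result.
#' @param path CSV path.
#' @return \code{path} (write) or a \code{calibration_table} (read).
#' @export
write_calibration_csv <- function(table, path) {
  df <- cbind(data.frame(sample_id = table$sample_ids),
              table$y,
              as.data.frame(table$X))
  names(df)[-(1:4)] <- sprintf("wl_%.6g", table$wavelengths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @param scale spectral scale label to attach on read.
#' @export
read_calibration_csv <- function(path, scale = "absorbance") {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  X <- as.matrix(df[wl_cols]); colnames(X) <- NULL
  structure(list(X = X,
                 y = df[c("protopectin", "water_soluble", "total")],
                 wavelengths = as.numeric(sub("^wl_", "", names(df)[wl_cols])),
                 sample_ids = as.character(df$sample_id),
                 scale = scale),
            class = "calibration_table")
}
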