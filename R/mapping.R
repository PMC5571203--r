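#' Pixel-wise distribution map
#'
#' Applies a calibrated model bundle to every masked pixel of a cube: the
#' bundle's recorded spectral scale (absorbance or reflectance) and
#' preprocessing steps are applied to each pixel spectrum, the bundle's
#' selected bands are extracted, and the model predicts the content.
#' Negative raw predictions are clipped to 0 (the physical floor); the
#' number of clipped pixels is reported and the unclipped values are kept
#' in a debug channel.
#'
#' @param cube a [hypercube()] of reflectance.
#' @param mask logical ROI mask, non-empty.
#' @param bundle a [calibrate_model()] bundle; its wavelength axis must
#'   match the cube's.
#' @return Object of class \code{"distribution_map"}: list with
#'   \code{values} (matrix, mg/g, NA outside the mask), \code{raw_values}
#'   (pre-clipping debug channel), \code{mask}, \code{component},
#'   \code{clip_count}, \code{model_label}.
#' @export
predict_map <- function(cube, mask, bundle) {
  pm_check(inherits(bundle, "model_bundle"), "bundle must be a model_bundle")
  if (length(cube$wavelengths) != length(bundle$wavelengths) ||
      max(abs(cube$wavelengths - bundle$wavelengths)) > 1e-6)
    pm_stop("cube wavelength axis does not match the model bundle",
            "incompatible_model")
  px <- extract_pixel_spectra(cube, mask)
  if (bundle$scale == "absorbance") px <- to_absorbance(px)
  px <- preprocess_matrix(px, bundle$preprocess)
  px <- px[, bundle$selection$selected, drop = FALSE]
  pred <- predict(bundle$model, px)
  clip_count <- sum(pred < 0)
  vals <- matrix(NA_real_, nrow(mask), ncol(mask))
  raw <- vals
  # extract_pixel_spectra uses raster (row-major) order
  ord <- which(t(mask))
  r <- (ord - 1L) %/% ncol(mask) + 1L
  c_ <- (ord - 1L) %% ncol(mask) + 1L
  idx <- cbind(r, c_)
  raw[idx] <- pred
  vals[idx] <- pmax(pred, 0)
  structure(list(values = vals, raw_values = raw, mask = mask,
                 component = bundle$target,
                 clip_count = as.integer(clip_count),
                 model_label = bundle$label),
            class = "distribution_map")
}

#' @export
print.distribution_map <- function(x, ...) {
  cat(sprintf("<distribution_map> %s (%s): %d px, %d clipped\n",
              x$component, x$model_label, sum(x$mask), x$clip_count))
  invisible(x)
}

#' Distribution-map statistics
#'
#' Moments (sample sd) and a histogram of the masked pixel contents.  Bins
#' start at 0 with width \code{bin_width} and cover the maximum value.
#'
#' @param map a [predict_map()] result.
#' @param bin_width histogram bin width in mg/g (> 0), default 0.25.
#' @return Object of class \code{"map_stats"}: \code{mean}, \code{sd},
#'   \code{min}, \code{max}, \code{histogram} (list: \code{breaks},
#'   \code{counts}).
#' @export
map_stats <- function(map, bin_width = 0.25) {
  pm_check(inherits(map, "distribution_map"), "map must be a
           distribution_map")
  pm_check(is_scalar_number(bin_width) && bin_width > 0,
           "bin_width must be > 0")
  v <- map$values[map$mask]
  if (length(v) == 0L) pm_stop("empty mask", "invalid_argument")
  breaks <- seq(0, bin_width * max(1, ceiling(max(v) / bin_width + 1e-12)),
                by = bin_width)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  structure(list(mean = mean(v), sd = stats::sd(v), min = min(v),
                 max = max(v),
                 histogram = list(breaks = breaks, counts = counts)),
            class = "map_stats")
}

# Piecewise-linear blue -> cyan -> green -> yellow -> red ramp at
# t = 0, 0.25, 0.5, 0.75, 1.
ramp_anchors <- matrix(c(0, 0, 1,
                         0, 1, 1,
                         0, 1, 0,
                         1, 1, 0,
                         1, 0, 0), ncol = 3L, byrow = TRUE)

pseudocolor_ramp <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  seg <- pmin(floor(t * 4), 3)
  f <- t * 4 - seg
  lo <- ramp_anchors[seg + 1L, , drop = FALSE]
  hi <- ramp_anchors[seg + 2L, , drop = FALSE]
  lo + f * (hi - lo)
}

#' Render a distribution map as a pseudo-color RGB image
#'
#' Linear color scale: a value v maps to position
#' t = clamp((v - vmin)/(vmax - vmin), 0, 1) on a piecewise-linear
#' blue-cyan-green-yellow-red ramp (low contents blue, high contents red).
#' Background (unmasked) pixels are rendered white.  The default display
#' range [1, 6] mg/g is fixed rather than auto-scaled so that slices are
#' directly comparable; pass \code{vmin}/\code{vmax} to rescale.
#'
#' @param map a [predict_map()] result.
#' @param vmin,vmax display range (mg/g), \code{vmax > vmin}.
#' @return Numeric array height x width x 3 of RGB values in [0, 1], with
#'   attribute \code{"colorbar"} holding a 256 x 1 x 3 color-bar strip
#'   (low at row 256, high at row 1).
#' @export
render_pseudocolor <- function(map, vmin = 1, vmax = 6) {
  pm_check(inherits(map, "distribution_map"), "map must be a
           distribution_map")
  if (!(is_scalar_number(vmin) && is_scalar_number(vmax) && vmax > vmin))
    pm_stop("vmax must exceed vmin", "invalid_argument")
  h <- nrow(map$values); w <- ncol(map$values)
  img <- array(1, dim = c(h, w, 3L))
  idx <- which(map$mask)
  t <- (map$values[idx] - vmin) / (vmax - vmin)
  rgb <- pseudocolor_ramp(t)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- rgb[, ch]
    img[, , ch] <- plane
  }
  bar <- pseudocolor_ramp(seq(1, 0, length.out = 256))
  attr(img, "colorbar") <- array(bar, dim = c(256L, 1L, 3L))
  img
}

#' Write a distribution map to disk
#'
#' Writes the float32 raster (single-band ENVI/BIL), the pseudo-color PNG
#' with its color-bar strip, and a one-row CSV of the map statistics.
#'
#' @param map a [predict_map()] result.
#' @param prefix output path prefix; files \code{<prefix>.bil/.bil.hdr},
#'   \code{<prefix>.png}, \code{<prefix>_colorbar.png},
#'   \code{<prefix>_stats.csv} are produced.
#' @param vmin,vmax display range forwarded to [render_pseudocolor()].
#' @param bin_width forwarded to [map_stats()].
#' @return Character vector of the written paths, invisibly.
#' @export
write_map <- function(map, prefix, vmin = 1, vmax = 6, bin_width = 0.25) {
  vals <- map$values
  vals[is.na(vals)] <- 0
  cube1 <- hypercube(array(vals, dim = c(dim(vals), 1L)), wavelengths = 1)
  raster <- paste0(prefix, ".bil")
  write_envi(cube1, raster)
  img <- render_pseudocolor(map, vmin, vmax)
  png_path <- paste0(prefix, ".png")
  png::writePNG(img, png_path)
  bar_path <- paste0(prefix, "_colorbar.png")
  png::writePNG(attr(img, "colorbar"), bar_path)
  st <- map_stats(map, bin_width)
  stats_path <- paste0(prefix, "_stats.csv")
  utils::write.csv(data.frame(component = map$component,
                              model = map$model_label,
                              mean = st$mean, sd = st$sd, min = st$min,
                              max = st$max, clip_count = map$clip_count),
                   stats_path, row.names = FALSE)
  invisible(c(raster, paste0(raster, ".hdr"), png_path, bar_path,
              stats_path))
}
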