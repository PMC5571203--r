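#' Synthetic scene configuration
#'
#' Bundles the data-generating assumptions of the synthetic imaging
#' experiment: two camera systems (set I, silicon CCD, 380--1030 nm, 512
#' bands; set II, InGaAs, 874--1734 nm, 256 bands), 64 slices per set,
#' smooth within-slice concentration fields, concentration-linked Gaussian
#' absorption bands, multiplicative/additive scatter and sensor noise.
#'
#' Per-slice mean protopectin contents are drawn uniformly on
#' \code{proto_range} (default 1--6 mg/g, the span of typical ripening
#' series) and water-soluble pectin means on \code{wsp_range}; total pectin
#' is their sum at every pixel by construction.  Within-slice heterogeneity
#' is a blurred white-noise field rescaled to standard deviation
#' \code{concentration_sd} (default 0.67 mg/g).
#'
#' @param spectral_set \code{"I"} (380--1030 nm, 512 bands) or \code{"II"}
#'   (874--1734 nm, 256 bands).
#' @param n_slices number of slices (one cube per slice).
#' @param image_height,image_width spatial size in pixels.
#' @param band_count number of spectral bands; defaults to 512 / 256 by set.
#' @param component_bands list with elements \code{protopectin} and
#'   \code{water_soluble}, each a data.frame with columns \code{center_nm},
#'   \code{width_nm}, \code{absorptivity} (per mg/g) describing Gaussian
#'   absorption profiles.
#' @param baseline_reflectance flesh reflectance at zero concentration.
#' @param background_reflectance constant reflectance of non-flesh pixels.
#' @param proto_range,wsp_range ranges (mg/g) for the uniform draw of
#'   per-slice mean contents.
#' @param concentration_sd within-slice standard deviation (mg/g).
#' @param field_smoothness Gaussian blur scale of the concentration field
#'   (pixels).
#' @param pit_fraction fractional radius of the central pit hole in the
#'   slice mask, in \code{[0, 0.5)}.
#' @param scatter_slope_sd,scatter_offset_sd per-pixel multiplicative and
#'   additive scatter scales (unitless / reflectance units).
#' @param noise_sd per-element sensor noise (reflectance units).
#' @param seed master seed; per-slice sub-seeds are derived from it.
#' @return An object of class \code{"scene_config"}.
#' @export
scene_config <- function(spectral_set = c("I", "II"),
                         n_slices = 64L,
                         image_height = 64L,
                         image_width = 64L,
                         band_count = NULL,
                         component_bands = default_component_bands(),
                         baseline_reflectance = 0.6,
                         background_reflectance = 0.02,
                         proto_range = c(1, 6),
                         wsp_range = c(0.5, 3),
                         concentration_sd = 0.67,
                         field_smoothness = 6,
                         pit_fraction = 0.12,
                         scatter_slope_sd = 0.05,
                         scatter_offset_sd = 0.01,
                         noise_sd = 0.003,
                         seed = 1L) {
  spectral_set <- match.arg(spectral_set)
  range_nm <- if (spectral_set == "I") c(380, 1030) else c(874, 1734)
  if (is.null(band_count))
    band_count <- if (spectral_set == "I") 512L else 256L
  pm_check(band_count >= 2, "band_count must be >= 2")
  pm_check(n_slices >= 1, "n_slices must be positive")
  pm_check(image_height > 0 && image_width > 0,
           "image dimensions must be positive")
  pm_check(baseline_reflectance > 0 && baseline_reflectance <= 1,
           "baseline_reflectance must lie in (0, 1]")
  pm_check(all(proto_range > 0) && all(wsp_range > 0) &&
             diff(proto_range) >= 0 && diff(wsp_range) >= 0,
           "concentration ranges must be positive and ordered")
  pm_check(concentration_sd >= 0, "concentration_sd must be >= 0")
  pm_check(noise_sd >= 0, "noise_sd must be >= 0")
  pm_check(pit_fraction >= 0 && pit_fraction < 0.5,
           "pit_fraction must be in [0, 0.5)")
  for (comp in c("protopectin", "water_soluble")) {
    cb <- component_bands[[comp]]
    pm_check(is.data.frame(cb) &&
               all(c("center_nm", "width_nm", "absorptivity") %in% names(cb)),
             "component_bands entries need center_nm/width_nm/absorptivity")
    pm_check(all(cb$width_nm > 0), "all band widths must be positive")
  }
  structure(list(
    spectral_set = spectral_set, n_slices = as.integer(n_slices),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    band_count = as.integer(band_count), range_nm = range_nm,
    component_bands = component_bands,
    baseline_reflectance = baseline_reflectance,
    background_reflectance = background_reflectance,
    proto_range = proto_range, wsp_range = wsp_range,
    concentration_sd = concentration_sd,
    field_smoothness = field_smoothness, pit_fraction = pit_fraction,
    scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd,
    noise_sd = noise_sd, seed = as.integer(seed)),
    class = "scene_config")
}

#' Default absorption bands of the two pectin components
#'
#' Gaussian absorption profiles anchored at the O--H overtone regions
#' (around 760, 980 and 1460 nm) and the C--H combination region near
#' 1200 nm, so that both camera ranges see at least one band per component.
#'
#' @return Named list of data.frames (\code{protopectin},
#'   \code{water_soluble}).
#' @export
default_component_bands <- function() {
  list(
    protopectin = data.frame(
      center_nm = c(980, 1460), width_nm = c(45, 55),
      absorptivity = c(0.050, 0.060)),
    water_soluble = data.frame(
      center_nm = c(760, 1200), width_nm = c(35, 50),
      absorptivity = c(0.040, 0.050)))
}

#' Elliptical slice mask with central pit
#'
#' Boolean grid emulating a fruit-slice cross-section: an ellipse inscribed
#' in the frame minus a concentric elliptical hole of fractional radius
#' \code{pit_fraction}.
#'
#' @param height,width frame size in pixels (positive).
#' @param pit_fraction fractional pit radius in \code{[0, 0.5)}; 0 gives a
#'   solid ellipse.
#' @return Logical \code{height x width} matrix with at least one TRUE.
#' @export
make_slice_mask <- function(height, width, pit_fraction = 0) {
  pm_check(is_scalar_number(height) && height > 0 &&
             is_scalar_number(width) && width > 0,
           "height and width must be positive")
  pm_check(pit_fraction >= 0 && pit_fraction < 0.5,
           "pit_fraction must be in [0, 0.5)")
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  ry <- height / 2; rx <- width / 2
  y <- matrix(seq_len(height), height, width)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  r2 <- ((y - cy) / ry)^2 + ((x - cx) / rx)^2
  mask <- r2 <= 1
  if (pit_fraction > 0) mask <- mask & (r2 > pit_fraction^2)
  pm_check(any(mask), "mask has no pixels")
  mask
}

# Separable Gaussian blur with reflection padding; sigma in pixels.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
    idx[idx < 1L] <- 1L; idx[idx > n] <- n
    padded <- v[idx]
    stats::filter(padded, k, sides = 2)[half + seq_len(n)]
  }
  out <- apply(mat, 2L, blur1d)
  t(apply(out, 1L, blur1d))
}

#' Smooth within-slice concentration field
#'
#' Blurred white noise rescaled so that the masked mean equals
#' \code{slice_mean} and the masked (sample) standard deviation equals
#' \code{config$concentration_sd}, then clipped at zero.  The number of
#' clipped pixels is attached as attribute \code{"clip_count"}.
#'
#' @param config a [scene_config()].
#' @param slice_mean target masked mean (mg/g, > 0).
#' @param mask logical grid; defaults to the config's elliptical slice mask.
#' @param seed RNG seed for the field draw.
#' @return Numeric matrix (mg/g); zero outside the mask.
#' @export
sample_concentration_field <- function(config, slice_mean, mask = NULL,
                                       seed = config$seed) {
  pm_check(is_scalar_number(slice_mean) && slice_mean > 0,
           "slice_mean must be > 0")
  if (is.null(mask))
    mask <- make_slice_mask(config$image_height, config$image_width,
                            config$pit_fraction)
  pm_check(any(mask), "empty mask")
  h <- nrow(mask); w <- ncol(mask)
  sdt <- config$concentration_sd
  if (sdt == 0) {
    field <- matrix(0, h, w); field[mask] <- slice_mean
    attr(field, "clip_count") <- 0L
    return(field)
  }
  raw <- withr::with_seed(seed, matrix(stats::rnorm(h * w), h, w))
  sm <- gaussian_blur(raw, config$field_smoothness)
  mu <- mean(sm[mask]); s <- stats::sd(sm[mask])
  pm_check(s > 0, "degenerate field (zero variance under mask)")
  field <- matrix(0, h, w)
  field[mask] <- (sm[mask] - mu) / s * sdt + slice_mean
  clipped <- sum(field[mask] < 0)
  field[field < 0] <- 0
  attr(field, "clip_count") <- as.integer(clipped)
  field
}

# Gaussian absorption profile of one component on a wavelength axis:
# A(lambda) = sum_b absorptivity_b * exp(-(lambda - center_b)^2/(2 width_b^2))
component_absorption <- function(bands_df, wavelengths) {
  a <- numeric(length(wavelengths))
  for (i in seq_len(nrow(bands_df))) {
    a <- a + bands_df$absorptivity[i] *
      exp(-((wavelengths - bands_df$center_nm[i])^2) /
            (2 * bands_df$width_nm[i]^2))
  }
  a
}

# Absorption matrix: bands x components for a config's wavelength axis.
absorption_matrix <- function(config) {
  wl <- band_wavelengths(config$range_nm[1L], config$range_nm[2L],
                         config$band_count)
  cbind(protopectin = component_absorption(config$component_bands$protopectin,
                                           wl),
        water_soluble = component_absorption(
          config$component_bands$water_soluble, wl))
}

#' Forward reflectance model of one pixel
#'
#' Beer-Lambert-style reflectance:
#' \deqn{R(\lambda) = slope \cdot baseline \cdot
#'   e^{-\sum_k c_k A_k(\lambda)} + offset + noise,}
#' with \eqn{A_k} the Gaussian absorption profile of component \eqn{k}.
#' Log-reflectance is therefore exactly linear in the concentrations when
#' scatter and noise vanish.
#'
#' @param concentrations named or positional vector
#'   \code{(protopectin, water_soluble)} in mg/g, non-negative.
#' @param config a [scene_config()].
#' @param scatter length-2 vector \code{(slope, offset)}; default no scatter.
#' @param noise_draw optional per-band noise vector (length
#'   \code{band_count}).
#' @return Reflectance spectrum of length \code{config$band_count}.
#' @export
forward_spectrum <- function(concentrations, config, scatter = c(1, 0),
                             noise_draw = NULL) {
  pm_check(length(concentrations) == 2L && all(is.finite(concentrations)),
           "two component concentrations required")
  if (any(concentrations < 0))
    pm_stop("concentrations must be non-negative", "invalid_argument")
  A <- absorption_matrix(config)
  base <- config$baseline_reflectance * exp(-as.numeric(A %*% concentrations))
  out <- scatter[1L] * base + scatter[2L]
  if (!is.null(noise_draw)) {
    pm_check(length(noise_draw) == config$band_count,
             "noise_draw length must equal band_count")
    out <- out + noise_draw
  }
  pm_check(all(is.finite(out)), "non-finite spectrum")
  out
}

# Generate one slice: cube + per-component fields + references.
generate_slice <- function(config, index, mask = NULL, A = NULL,
                           means = NULL) {
  if (is.null(mask))
    mask <- make_slice_mask(config$image_height, config$image_width,
                            config$pit_fraction)
  if (is.null(A)) A <- absorption_matrix(config)
  seed0 <- derive_seed(config$seed, index * 7L)
  if (is.null(means)) {
    means <- withr::with_seed(seed0, c(
      proto = stats::runif(1, config$proto_range[1L],
                           config$proto_range[2L]),
      wsp = stats::runif(1, config$wsp_range[1L], config$wsp_range[2L])))
  } else {
    pm_check(length(means) == 2L && all(means > 0),
             "means must be two positive slice means (proto, wsp)")
    means <- c(proto = unname(means[1L]), wsp = unname(means[2L]))
  }
  f_proto <- sample_concentration_field(config, means[["proto"]], mask,
                                        seed = derive_seed(config$seed,
                                                           index * 7L + 1L))
  f_wsp <- sample_concentration_field(config, means[["wsp"]], mask,
                                      seed = derive_seed(config$seed,
                                                         index * 7L + 2L))
  h <- config$image_height; w <- config$image_width
  b <- config$band_count
  npix <- sum(mask)
  draws <- withr::with_seed(derive_seed(config$seed, index * 7L + 3L), list(
    slope = 1 + stats::rnorm(npix, 0, config$scatter_slope_sd),
    offset = stats::rnorm(npix, 0, config$scatter_offset_sd),
    noise = matrix(stats::rnorm(npix * b, 0, config$noise_sd), npix, b)))
  if (config$scatter_slope_sd == 0) draws$slope <- rep(1, npix)
  if (config$scatter_offset_sd == 0) draws$offset <- rep(0, npix)
  if (config$noise_sd == 0) draws$noise <- matrix(0, npix, b)
  conc <- cbind(f_proto[mask], f_wsp[mask])           # npix x 2
  spectra <- draws$slope * config$baseline_reflectance *
    exp(-tcrossprod(conc, A)) + draws$offset + draws$noise
  vals <- array(config$background_reflectance, dim = c(h, w, b))
  idx <- which(mask)                                   # column-major pixel ids
  for (j in seq_len(b)) {
    plane <- vals[, , j]
    plane[idx] <- spectra[, j]
    vals[, , j] <- plane
  }
  wl <- band_wavelengths(config$range_nm[1L], config$range_nm[2L], b)
  list(cube = hypercube(vals, wl),
       mask = mask,
       fields = list(protopectin = f_proto, water_soluble = f_wsp,
                     total = f_proto + f_wsp),
       references = c(protopectin = reference_value(f_proto, mask),
                      water_soluble = reference_value(f_wsp, mask),
                      total = reference_value(f_proto + f_wsp, mask)))
}

#' Generate a synthetic imaging scene
#'
#' Produces \code{n_slices} hypercubes by applying the forward reflectance
#' model pixel-wise to smooth concentration fields, plus the ground truth
#' the downstream analysis is validated against.  Deterministic under the
#' config's master seed (per-slice sub-seeds are derived from it), and total
#' pectin equals protopectin + water-soluble pectin at every pixel and every
#' slice mean exactly.
#'
#' @param config a [scene_config()].
#' @return List with elements \code{cubes} (list of [hypercube()]),
#'   \code{truth}: list with \code{masks}, \code{fields} (per slice, per
#'   component matrices) and \code{references} (data.frame with columns
#'   \code{sample_id}, \code{protopectin}, \code{water_soluble},
#'   \code{total}, mg/g).
#' @export
generate_scene <- function(config) {
  mask <- make_slice_mask(config$image_height, config$image_width,
                          config$pit_fraction)
  A <- absorption_matrix(config)
  slices <- lapply(seq_len(config$n_slices), function(i)
    generate_slice(config, i, mask = mask, A = A))
  refs <- do.call(rbind, lapply(slices, function(s)
    as.data.frame(as.list(s$references))))
  refs <- cbind(sample_id = sprintf("slice_%03d", seq_len(config$n_slices)),
                refs)
  rownames(refs) <- NULL
  list(cubes = lapply(slices, `[[`, "cube"),
       truth = list(masks = lapply(slices, `[[`, "mask"),
                    fields = lapply(slices, `[[`, "fields"),
                    references = refs))
}

#' Simulate a single slice
#'
#' Generates one slice of a scene (cube, mask, ground-truth fields and
#' reference values), optionally with prescribed slice-mean contents
#' instead of the config's random draw — useful for reproducing a specific
#' example slice (e.g. a slice with a mean protopectin content of
#' 2.67 mg/g).
#'
#' @param config a [scene_config()].
#' @param index slice index (drives the per-slice sub-seed).
#' @param means optional length-2 vector of slice means
#'   \code{(protopectin, water_soluble)} in mg/g.
#' @return List with \code{cube}, \code{mask}, \code{fields} (per-component
#'   matrices) and \code{references} (named vector, mg/g).
#' @export
simulate_slice <- function(config, index = 1L, means = NULL) {
  pm_check(inherits(config, "scene_config"), "config must be a scene_config")
  generate_slice(config, as.integer(index), means = means)
}

#' Slice-level reference value
#'
#' Arithmetic mean of a concentration field over the masked pixels: the
#' synthetic stand-in for the slice-level wet-chemistry assay value.
#'
#' @param field numeric matrix (mg/g).
#' @param mask logical matrix of the same shape, at least one TRUE.
#' @return Scalar mean (mg/g).
#' @export
reference_value <- function(field, mask) {
  pm_check(identical(dim(field), dim(mask)), "field/mask shape mismatch")
  if (!any(mask)) pm_stop("empty mask", "invalid_argument")
  mean(field[mask])
}
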