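#' Simulate a scene and build its calibration table in one pass
#'
#' Streams the scene slice by slice: each slice's cube is generated,
#' segmented with [threshold_segment()], reduced to its slice-level mean
#' spectrum, and discarded — so arbitrarily large scenes fit in memory.
#' The first \code{keep_slices} slices are retained in full (cube, ROI
#' mask, ground-truth fields) for downstream mapping and validation.
#'
#' @param config a [scene_config()].
#' @param segment_threshold reflectance threshold for flesh/background
#'   separation.
#' @param keep_slices number of leading slices to keep in full.
#' @param scale spectral scale of the table, see
#'   [build_calibration_table()].
#' @return List with \code{table} (a \code{calibration_table}),
#'   \code{kept} (list of \code{list(cube, mask, truth, index)}), and
#'   \code{config}.
#' @export
simulate_calibration_table <- function(config, segment_threshold = 0.1,
                                       keep_slices = 0L,
                                       scale = c("absorbance",
                                                 "reflectance")) {
  scale <- match.arg(scale)
  pm_check(inherits(config, "scene_config"), "config must be a scene_config")
  mask0 <- make_slice_mask(config$image_height, config$image_width,
                           config$pit_fraction)
  A <- absorption_matrix(config)
  specs <- vector("list", config$n_slices)
  refs <- vector("list", config$n_slices)
  kept <- list()
  for (i in seq_len(config$n_slices)) {
    sl <- generate_slice(config, i, mask = mask0, A = A)
    roi <- threshold_segment(sl$cube, threshold = segment_threshold)
    px <- extract_pixel_spectra(sl$cube, roi)
    if (scale == "absorbance") px <- to_absorbance(px)
    specs[[i]] <- colMeans(px)
    refs[[i]] <- sl$references
    if (i <= keep_slices)
      kept[[i]] <- list(cube = sl$cube, mask = roi, truth = sl$fields,
                        index = i)
  }
  references <- cbind(
    data.frame(sample_id = sprintf("%s_slice_%03d", config$spectral_set,
                                   seq_len(config$n_slices))),
    as.data.frame(do.call(rbind, refs)))
  table <- structure(list(
    X = do.call(rbind, specs),
    y = references[c("protopectin", "water_soluble", "total")],
    wavelengths = band_wavelengths(config$range_nm[1L], config$range_nm[2L],
                                   config$band_count),
    sample_ids = references$sample_id,
    scale = scale), class = "calibration_table")
  list(table = table, kept = kept, config = config)
}
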