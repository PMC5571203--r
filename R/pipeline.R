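#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of a full simulated
#' experiment: scene parameters per spectral set, grid axes, selector
#' parameters, targets, output directory and master seed.  Accepts a named
#' list of overrides or a YAML/JSON file with the same keys; unspecified
#' keys take the defaults of the simulated study (64 slices per set,
#' 64 x 64 px, 512/256 bands, all five selection strategies, both
#' calibration methods, raw and preprocessed arms, protopectin target).
#'
#' @param config named list of overrides, or a path to a YAML/JSON file.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    pm_check(file.exists(config), sprintf("config file not found: %s",
                                          config))
    config <- yaml::read_yaml(config)
  }
  pm_check(is.list(config), "config must be a list or a file path")
  defaults <- list(
    sets = c("I", "II"),
    n_slices = 64L,
    image_height = 64L, image_width = 64L,
    noise_sd = 0.003, scatter_slope_sd = 0.05, scatter_offset_sd = 0.01,
    concentration_sd = 0.67,
    band_count = NULL,                 # per-set defaults (512 / 256)
    selections = c("full", "spa", "uve", "uve_spa", "cars"),
    methods = c("plsr", "lssvm"),
    preprocess_arms = list(raw = "none", pre = c("sg:7:2", "snv")),
    selector_params = list(),
    targets = "protopectin",
    segment_threshold = 0.1,
    map_slices = 4L,
    map_range = c(1, 6),
    write_cubes = "mapped",            # "mapped", "all" or "none"
    out_dir = tempfile("pectinmap_run_"),
    seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  for (key in c("n_slices", "image_height", "image_width", "map_slices",
                "seed"))
    cfg[[key]] <- as.integer(cfg[[key]])
  pm_check(all(cfg$targets %in% c("protopectin", "water_soluble", "total")),
           "unknown target")
  pm_check(cfg$write_cubes %in% c("mapped", "all", "none"),
           "write_cubes must be 'mapped', 'all' or 'none'")
  pm_check(cfg$seed == round(cfg$seed), "seed must be an integer")
  structure(cfg, class = "pipeline_config")
}

log_line <- function(log_path, stage, msg) {
  line <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}

#' Run the end-to-end simulated experiment
#'
#' Executes the whole study: simulate scenes per spectral set -> segment
#' flesh pixels -> extract slice-level spectra -> build calibration tables
#' -> run the model grid per target -> pick the best model -> predict and
#' render distribution maps for a subset of slices.  Every artifact written
#' is listed in the returned (and saved) manifest with a content hash;
#' rerunning with the same config and seed reproduces the numeric artifacts
#' byte-identically.
#'
#' Scenes are generated slice by slice so only the mapped slices' cubes are
#' held in memory.
#'
#' @param config a [pipeline_config()], a named list of overrides, or a
#'   YAML/JSON config path.
#' @return The manifest: list with \code{artifacts} (data.frame of path,
#'   bytes, md5), \code{best} (per target, per set best model labels),
#'   \code{out_dir}, \code{seed}, invisibly also saved to
#'   \code{manifest.json}.
#' @export
run_experiment <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  artifacts <- character(0)
  add_artifact <- function(paths) artifacts <<- c(artifacts, paths)
  t0 <- Sys.time()

  tables <- list()
  map_data <- list()
  for (set in config$sets) {
    sc <- scene_config(
      spectral_set = set, n_slices = config$n_slices,
      image_height = config$image_height, image_width = config$image_width,
      band_count = config$band_count,
      concentration_sd = config$concentration_sd,
      noise_sd = config$noise_sd,
      scatter_slope_sd = config$scatter_slope_sd,
      scatter_offset_sd = config$scatter_offset_sd,
      seed = derive_seed(config$seed, match(set, c("I", "II"))))
    log_line(log_path, "simulate",
             sprintf("set=%s n_slices=%d seed=%d", set, sc$n_slices,
                     sc$seed))
    n_map <- min(config$map_slices, sc$n_slices)
    keep_n <- if (config$write_cubes == "all") sc$n_slices else n_map
    sim <- simulate_calibration_table(
      sc, segment_threshold = config$segment_threshold,
      keep_slices = keep_n)
    kept <- sim$kept
    if (config$write_cubes != "none") {
      for (sl in kept) {
        cube_path <- file.path(out, sprintf("cube_%s_%03d.bil", set,
                                            sl$index))
        write_envi(sl$cube, cube_path)
        add_artifact(c(cube_path, paste0(cube_path, ".hdr")))
      }
    }
    kept <- kept[seq_len(n_map)]
    references <- cbind(data.frame(sample_id = sim$table$sample_ids),
                        sim$table$y)
    ref_path <- file.path(out, sprintf("references_%s.csv", set))
    utils::write.csv(references, ref_path, row.names = FALSE)
    add_artifact(ref_path)
    X <- sim$table$X
    tables[[set]] <- sim$table
    tab_path <- file.path(out, sprintf("calibration_table_%s.csv", set))
    write_calibration_csv(tables[[set]], tab_path)
    add_artifact(tab_path)
    map_data[[set]] <- kept
    log_line(log_path, "extract",
             sprintf("set=%s table %d x %d", set, nrow(X), ncol(X)))
  }

  best <- list()
  for (target in config$targets) {
    log_line(log_path, "calibrate", sprintf("target=%s grid start", target))
    arms <- lapply(config$preprocess_arms, preprocess_spec)
    grid <- run_model_grid(tables, target = target,
                           selections = config$selections,
                           methods = config$methods,
                           preprocess_arms = arms,
                           selector_params = config$selector_params,
                           seed = derive_seed(config$seed, 97L))
    grid_csv <- file.path(out, sprintf("grid_%s.csv", target))
    grid_json <- file.path(out, sprintf("grid_%s.json", target))
    write_grid(grid, grid_csv, grid_json)
    add_artifact(c(grid_csv, grid_json))
    bundle <- grid$best_bundle
    bundle_path <- file.path(out, sprintf("best_model_%s.json", target))
    save_model_bundle(bundle, bundle_path)
    add_artifact(bundle_path)
    sel_csv <- file.path(out, sprintf("selected_bands_%s.csv", target))
    write_selection_csv(bundle$selection, bundle$wavelengths, sel_csv)
    add_artifact(sel_csv)
    best[[target]] <- list(label = grid$best,
                           rpd = grid$cells$rpd[
                             grid$cells$model_label == grid$best],
                           n_bands = length(bundle$selection$selected))
    log_line(log_path, "evaluate",
             sprintf("target=%s best=%s", target, grid$best))
    best_set <- grid$cells$set[grid$cells$model_label == grid$best]
    for (sl in map_data[[best_set]]) {
      map <- predict_map(sl$cube, sl$mask, bundle)
      prefix <- file.path(out, sprintf("map_%s_%s_%03d", target, best_set,
                                       sl$index))
      add_artifact(write_map(map, prefix, vmin = config$map_range[1L],
                             vmax = config$map_range[2L]))
    }
    log_line(log_path, "map",
             sprintf("target=%s slices=%d", target,
                     length(map_data[[best_set]])))
  }

  cfg_path <- file.path(out, "config.json")
  cfg_list <- unclass(config)
  cfg_list$out_dir <- NULL
  jsonlite::write_json(cfg_list, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  add_artifact(cfg_path)
  man <- data.frame(path = basename(artifacts),
                    bytes = file.info(artifacts)$size,
                    md5 = unname(tools::md5sum(artifacts)))
  manifest <- list(artifacts = man, best = best, out_dir = out,
                   seed = config$seed,
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_line(log_path, "done",
           sprintf("artifacts=%d elapsed=%.1fs", nrow(man),
                   manifest$elapsed_sec))
  invisible(manifest)
}
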