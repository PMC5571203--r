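#' Calibration / cross-validation metrics
#'
#' Computes the standard chemometric report for one model: RMSEC and RMSECV
#' (root mean square errors of calibration and of leave-one-out
#' cross-validation, mg/g), Pearson correlations r_cal and r_cv, the
#' residual predictive deviation RPD = sd(y_ref)/RMSECV (sample sd, n-1),
#' and the robustness indicator AB_RMSE = |RMSEC - RMSECV| (small values
#' indicate a model that does not overfit).  A perfect cross-validation
#' (RMSECV = 0) yields \code{rpd = Inf}, serialized as the string
#' \code{"Inf"} in JSON exports.
#'
#' @param y_ref reference values (mg/g), length >= 3, non-constant.
#' @param y_cal fitted (calibration) predictions.
#' @param y_cv leave-one-out cross-validated predictions.
#' @return Object of class \code{"metrics_report"}: list with \code{rmsec},
#'   \code{rmsecv}, \code{r_cal}, \code{r_cv}, \code{rpd}, \code{ab_rmse},
#'   \code{n}.
#' @export
compute_metrics <- function(y_ref, y_cal, y_cv) {
  n <- length(y_ref)
  pm_check(n >= 3 && length(y_cal) == n && length(y_cv) == n,
           "y_ref, y_cal, y_cv must share length >= 3")
  if (stats::sd(y_ref) == 0)
    pm_stop("constant reference values: r and RPD undefined",
            "degenerate_target")
  rmsec <- rmse(y_ref, y_cal)
  rmsecv <- rmse(y_ref, y_cv)
  structure(list(
    rmsec = rmsec, rmsecv = rmsecv,
    r_cal = stats::cor(y_ref, y_cal),
    r_cv = stats::cor(y_ref, y_cv),
    rpd = if (rmsecv == 0) Inf else stats::sd(y_ref) / rmsecv,
    ab_rmse = abs(rmsec - rmsecv),
    n = n), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report>%s RMSEC %.4g  RMSECV %.4g  ",
                     "r_cal %.3f  r_cv %.3f  RPD %.3f  AB_RMSE %.4g\n"),
              if (is.null(x$model_label)) "" else paste0(" ", x$model_label),
              x$rmsec, x$rmsecv, x$r_cal, x$r_cv, x$rpd, x$ab_rmse))
  invisible(x)
}

#' Model specification (one grid cell)
#'
#' Describes one calibration pipeline cell: calibration method,
#' preprocessing, and wavelength selection strategy.
#'
#' @param method \code{"plsr"} or \code{"lssvm"}.
#' @param preprocess a [preprocess_spec()] or character step vector.
#' @param selection a \code{selection_result}, a selector name
#'   (\code{"full"}, \code{"spa"}, \code{"uve"}, \code{"uve_spa"},
#'   \code{"cars"}), or an integer vector of band indices.
#' @param selector_params named list of extra arguments for the selector.
#' @param label optional model label; autogenerated otherwise.
#' @return Object of class \code{"model_spec"}.
#' @export
model_spec <- function(method = c("plsr", "lssvm"),
                       preprocess = preprocess_spec("none"),
                       selection = "full",
                       selector_params = list(),
                       label = NULL) {
  method <- match.arg(method)
  if (is.character(preprocess)) preprocess <- preprocess_spec(preprocess)
  if (is.numeric(selection)) {
    pm_check(length(selection) >= 1 && !anyDuplicated(selection) &&
               all(selection >= 1),
             "selected_bands must be non-empty, unique, positive")
    selection <- new_selection_result("manual", selection)
  }
  if (is.character(selection))
    pm_check(selection %in% c("full", "spa", "uve", "uve_spa", "cars"),
             "unknown selection strategy")
  structure(list(method = method, preprocess = preprocess,
                 selection = selection, selector_params = selector_params,
                 label = label),
            class = "model_spec")
}

run_selector <- function(name, X, y, params, seed) {
  switch(name,
    full = full_selection(ncol(X)),
    spa = do.call(spa_select, c(list(X = X, y = y), params)),
    uve = do.call(uve_select, c(list(X = X, y = y, seed = seed), params)),
    uve_spa = do.call(uve_spa_select,
                      c(list(X = X, y = y, seed = seed), params)),
    cars = do.call(cars_select, c(list(X = X, y = y, seed = seed), params)))
}

#' Calibrate one model cell and package it for prediction
#'
#' Runs the fixed pipeline order preprocess -> restrict to selected bands ->
#' tune hyperparameters by LOO -> fit on all samples, and returns a
#' self-contained model bundle carrying the full provenance (preprocessing
#' steps, selected band indices, wavelength axis, spectral scale) needed to
#' reproduce the exact pipeline on new pixels.
#'
#' @param table a [build_calibration_table()] result.
#' @param spec a [model_spec()].
#' @param target \code{"protopectin"}, \code{"water_soluble"} or
#'   \code{"total"}.
#' @param seed seed for stochastic selectors.
#' @return Object of class \code{"model_bundle"} with the fitted model, the
#'   tuned hyperparameters, calibration and cross-validated predictions,
#'   the [compute_metrics()] report, and provenance fields.
#' @export
calibrate_model <- function(table, spec,
                            target = c("protopectin", "water_soluble",
                                       "total"),
                            seed = 1L) {
  target <- match.arg(target)
  pm_check(inherits(table, "calibration_table"), "table must be a
           calibration_table")
  pm_check(inherits(spec, "model_spec"), "spec must be a model_spec")
  y <- table$y[[target]]
  stage <- function(name, expr) {
    tryCatch(expr, pectinmap_error = function(e)
      pm_stop(sprintf("[%s] %s", name, conditionMessage(e)),
              sub("^pectinmap_", "", class(e)[1L])))
  }
  Xp <- stage("preprocess", preprocess_matrix(table$X, spec$preprocess))
  sel <- spec$selection
  if (is.character(sel))
    sel <- stage("selection",
                 run_selector(sel, Xp, y, spec$selector_params, seed))
  pm_check(inherits(sel, "selection_result"), "invalid selection")
  if (max(sel$selected) > ncol(Xp))
    pm_stop("selected band indices exceed the band count",
            "invalid_argument")
  Xs <- Xp[, sel$selected, drop = FALSE]
  tuned <- stage("tuning", tune_hyperparameters(Xs, y, spec$method))
  model <- stage("fit", if (spec$method == "plsr") {
    fit_plsr(Xs, y, tuned$hyperparams$n_latent)
  } else {
    fit_lssvm(Xs, y, tuned$hyperparams$gamma, tuned$hyperparams$sigma2)
  })
  y_cal <- predict(model, Xs)
  metrics <- compute_metrics(y, y_cal, tuned$cv_predictions)
  label <- spec$label %||% paste(sel$method, spec$method,
                                 if (identical(spec$preprocess$labels,
                                               "none")) "raw" else "pre",
                                 sep = "-")
  metrics$model_label <- label
  metrics$n_bands_used <- length(sel$selected)
  metrics$hyperparams <- tuned$hyperparams
  structure(list(model = model, method = spec$method,
                 hyperparams = tuned$hyperparams,
                 preprocess = spec$preprocess,
                 selection = sel,
                 wavelengths = table$wavelengths,
                 scale = table$scale,
                 target = target,
                 y_cal = y_cal, y_cv = tuned$cv_predictions,
                 metrics = metrics, label = label,
                 version = "pectinmap-bundle-1"),
            class = "model_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate one model cell
#'
#' Convenience wrapper around [calibrate_model()] returning only the
#' [compute_metrics()] report (with \code{model_label},
#' \code{n_bands_used} and \code{hyperparams} attached).
#'
#' @inheritParams calibrate_model
#' @return A \code{metrics_report}.
#' @export
evaluate_model <- function(table, spec,
                           target = c("protopectin", "water_soluble",
                                      "total"),
                           seed = 1L) {
  calibrate_model(table, spec, target, seed)$metrics
}

#' Run the full model-comparison grid
#'
#' Evaluates every cell of spectral set x selection strategy x calibration
#' method x preprocessing arm for one pectin target.  Selection is re-run
#' once per (set, preprocessing arm) and shared between the two calibration
#' methods of that arm.  The best cell maximizes RPD; ties prefer fewer
#' bands, then PLSR.  A failing cell is recorded with its error message and
#' the grid completes.
#'
#' @param tables named list of [build_calibration_table()]s, e.g.
#'   \code{list(I = ..., II = ...)}.
#' @param target pectin component.
#' @param selections selector names to include.
#' @param methods calibration methods to include.
#' @param preprocess_arms named list of [preprocess_spec()]s; default
#'   \code{raw} (none) and \code{pre} (SG(7,2) then SNV).
#' @param selector_params named list of per-selector parameter lists.
#' @param seed seed for stochastic selectors.
#' @param keep_bundles if TRUE, keep every cell's \code{model_bundle}
#'   (memory-heavy); the best cell's bundle is always kept.
#' @return Object of class \code{"model_grid"}: list with \code{cells}
#'   (data.frame, one row per cell), \code{reports}, \code{best} (label),
#'   \code{best_bundle}, \code{target}, \code{axes}.
#' @export
run_model_grid <- function(tables,
                           target = c("protopectin", "water_soluble",
                                      "total"),
                           selections = c("full", "spa", "uve", "uve_spa",
                                          "cars"),
                           methods = c("plsr", "lssvm"),
                           preprocess_arms = list(
                             raw = preprocess_spec("none"),
                             pre = preprocess_spec(c("sg:7:2", "snv"))),
                           selector_params = list(),
                           seed = 1L,
                           keep_bundles = FALSE) {
  target <- match.arg(target)
  pm_check(is.list(tables) && length(tables) >= 1 &&
             !is.null(names(tables)), "tables must be a named list")
  rows <- list(); reports <- list(); bundles <- list()
  for (set in names(tables)) {
    tab <- tables[[set]]
    y <- tab$y[[target]]
    for (arm in names(preprocess_arms)) {
      prep <- preprocess_arms[[arm]]
      Xp <- preprocess_matrix(tab$X, prep)
      sel_results <- list()
      for (selname in selections) {
        sel_results[[selname]] <- tryCatch(
          run_selector(selname, Xp, y,
                       selector_params[[selname]] %||% list(), seed),
          pectinmap_error = function(e) e)
      }
      for (selname in selections) for (method in methods) {
        label <- paste(selname, method, set, arm, sep = "-")
        sr <- sel_results[[selname]]
        rep_ <- if (inherits(sr, "error")) sr else tryCatch({
          spec <- model_spec(method, prep, sr, label = label)
          calibrate_model(tab, spec, target, seed)
        }, pectinmap_error = function(e) e)
        if (inherits(rep_, "error")) {
          rows[[label]] <- data.frame(
            set = set, selection = selname, method = method,
            preprocess = arm, model_label = label, n_bands = NA_integer_,
            rmsec = NA_real_, rmsecv = NA_real_, r_cal = NA_real_,
            r_cv = NA_real_, rpd = NA_real_, ab_rmse = NA_real_,
            error = conditionMessage(rep_))
        } else {
          m <- rep_$metrics
          rows[[label]] <- data.frame(
            set = set, selection = selname, method = method,
            preprocess = arm, model_label = label,
            n_bands = m$n_bands_used, rmsec = m$rmsec, rmsecv = m$rmsecv,
            r_cal = m$r_cal, r_cv = m$r_cv, rpd = m$rpd,
            ab_rmse = m$ab_rmse, error = NA_character_)
          reports[[label]] <- m
          if (keep_bundles) bundles[[label]] <- rep_
          else bundles[[label]] <- NULL
          # retain the bundle only if currently best (memory control)
          if (!keep_bundles) {
            cur <- attr(bundles, "best_tmp")
            better <- is.null(cur) || m$rpd > cur$metrics$rpd ||
              (m$rpd == cur$metrics$rpd &&
                 (m$n_bands_used < cur$metrics$n_bands_used ||
                    (m$n_bands_used == cur$metrics$n_bands_used &&
                       method == "plsr")))
            if (better) attr(bundles, "best_tmp") <- rep_
          }
        }
      }
    }
  }
  cells <- do.call(rbind, rows); rownames(cells) <- NULL
  ok <- !is.na(cells$rpd)
  pm_check(any(ok), "every grid cell failed")
  cand <- cells[ok, ]
  ord <- order(-cand$rpd, cand$n_bands,
               match(cand$method, c("plsr", "lssvm")))
  best_label <- cand$model_label[ord[1L]]
  best_bundle <- if (keep_bundles) bundles[[best_label]] else
    attr(bundles, "best_tmp")
  structure(list(cells = cells, reports = reports, best = best_label,
                 best_bundle = best_bundle,
                 bundles = if (keep_bundles) bundles else NULL,
                 target = target,
                 axes = list(sets = names(tables), selections = selections,
                             methods = methods,
                             preprocess = names(preprocess_arms))),
            class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  cat(sprintf("<model_grid> target %s: %d cells, best = %s\n",
              x$target, nrow(x$cells), x$best))
  invisible(x)
}

#' Mean selected-band percentage
#'
#' Worked-example summary statistic: the mean, over spectral sets, of the
#' selected band count as a percentage of the full band count.  E.g. 8 of
#' 512 and 4 of 256 both give 1.5625%, so the mean is 1.5625 (~1.56%).
#'
#' @param counts selected band counts per set.
#' @param totals full band counts per set.
#' @return Percentage (scalar).
#' @export
selected_band_percentage <- function(counts, totals) {
  pm_check(length(counts) == length(totals) && all(totals > 0),
           "counts and totals must align, totals > 0")
  mean(counts / totals) * 100
}

#' Mean-RMSECV percentage ratio between detector sets
#'
#' Worked-example summary statistic: 100 x mean(RMSECV of set I) /
#' mean(RMSECV of set II), e.g. 100 x 0.300 / 0.646 = 46.4 (~46%).
#'
#' @param rmsecv_I,rmsecv_II RMSECV values of the two sets.
#' @return Percentage (scalar).
#' @export
rmsecv_set_ratio <- function(rmsecv_I, rmsecv_II) {
  pm_check(all(rmsecv_II > 0), "set II RMSECVs must be positive")
  100 * mean(rmsecv_I) / mean(rmsecv_II)
}

#' Summarize a model grid
#'
#' Per-axis marginal means of RPD and RMSECV, the mean selected-band
#' percentage per selection strategy (via [selected_band_percentage()]),
#' and the mean-RMSECV percentage ratio between the first two spectral sets
#' (via [rmsecv_set_ratio()]).
#'
#' @param grid a [run_model_grid()] result.
#' @return List with \code{marginals} (list of data.frames per axis),
#'   \code{band_percentage} (named by selection strategy) and
#'   \code{set_rmsecv_ratio} (NA when fewer than two sets).
#' @export
summarize_grid <- function(grid) {
  pm_check(inherits(grid, "model_grid"), "grid must be a model_grid")
  cells <- grid$cells[!is.na(grid$cells$rpd), ]
  pm_check(nrow(cells) >= 1, "grid has no successful cells")
  marg <- function(axis) {
    agg <- stats::aggregate(cells[c("rpd", "rmsecv")],
                            by = cells[axis], FUN = mean)
    names(agg)[1L] <- axis
    agg
  }
  marginals <- lapply(stats::setNames(nm = c("set", "selection", "method",
                                             "preprocess")), marg)
  full_counts <- stats::aggregate(n_bands ~ set,
                                  data = cells[cells$selection == "full", ],
                                  FUN = mean)
  band_pct <- sapply(unique(cells$selection), function(s) {
    sub <- stats::aggregate(n_bands ~ set,
                            data = cells[cells$selection == s, ], FUN = mean)
    m <- merge(sub, full_counts, by = "set", suffixes = c("", "_full"))
    selected_band_percentage(m$n_bands, m$n_bands_full)
  })
  sets <- grid$axes$sets
  ratio <- if (length(sets) >= 2) {
    rmsecv_set_ratio(cells$rmsecv[cells$set == sets[1L]],
                     cells$rmsecv[cells$set == sets[2L]])
  } else NA_real_
  list(marginals = marginals, band_percentage = band_pct,
       set_rmsecv_ratio = ratio)
}

#' Export a model grid as CSV and JSON
#'
#' CSV rows list selection x method x preprocessing per set with metric
#' columns, one row per grid cell; the JSON carries the same
#' cells plus the best-model label.  Infinite RPD values are written as the
#' string \code{"Inf"}.
#'
#' @param grid a [run_model_grid()] result.
#' @param csv_path,json_path output paths (NULL to skip either).
#' @export
write_grid <- function(grid, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(grid$cells, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    cells <- grid$cells
    cells$rpd <- ifelse(is.infinite(cells$rpd), "Inf", cells$rpd)
    jsonlite::write_json(list(target = grid$target, best = grid$best,
                              cells = cells),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(grid)
}
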