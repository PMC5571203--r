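#' Save / load a calibrated model bundle
#'
#' Bundles are serialized as versioned JSON carrying the fitted model's
#' numeric state (PLSR: means, weights, loadings, coefficient path; LS-SVM:
#' dual coefficients, bias, kernel parameters and training spectra) together
#' with the full pipeline provenance: preprocessing steps, selected band
#' indices, wavelength axis, spectral scale and target, so that
#' [predict_map()] can reproduce the exact pipeline on new pixels.
#'
#' @param bundle a [calibrate_model()] result.
#' @param path JSON output path.
#' @return \code{path} (save) / a \code{model_bundle} (load).
#' @export
save_model_bundle <- function(bundle, path) {
  pm_check(inherits(bundle, "model_bundle"), "bundle must be a model_bundle")
  model <- bundle$model
  model_fields <- if (bundle$method == "plsr") {
    list(n_latent = model$n_latent, x_mean = model$x_mean,
         y_mean = model$y_mean, weights = model$weights,
         x_loadings = model$x_loadings, y_loadings = model$y_loadings,
         coef_path = model$coef_path, coefficients = model$coefficients,
         intercept = model$intercept)
  } else {
    list(alpha = model$alpha, bias = model$bias, gamma = model$gamma,
         sigma2 = model$sigma2, X_train = model$X_train)
  }
  metrics <- bundle$metrics
  metrics$rpd <- if (is.infinite(metrics$rpd)) "Inf" else metrics$rpd
  obj <- list(version = bundle$version, method = bundle$method,
              hyperparams = bundle$hyperparams,
              preprocess = bundle$preprocess$labels,
              selection = list(method = bundle$selection$method,
                               selected = bundle$selection$selected),
              wavelengths = bundle$wavelengths, scale = bundle$scale,
              target = bundle$target, label = bundle$label,
              metrics = metrics[c("rmsec", "rmsecv", "r_cal", "r_cv",
                                  "rpd", "ab_rmse", "n")],
              model = model_fields)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pm_check(identical(obj$version, "pectinmap-bundle-1"),
           "unrecognized bundle version", class = "incompatible_model")
  mf <- obj$model
  as_mat <- function(m) if (is.list(m)) do.call(cbind, m) else as.matrix(m)
  model <- if (obj$method == "plsr") {
    structure(list(n_latent = as.integer(mf$n_latent),
                   x_mean = as.numeric(mf$x_mean),
                   y_mean = as.numeric(mf$y_mean),
                   weights = as_mat(mf$weights),
                   x_loadings = as_mat(mf$x_loadings),
                   y_loadings = as.numeric(mf$y_loadings),
                   coef_path = as_mat(mf$coef_path),
                   coefficients = as.numeric(mf$coefficients),
                   intercept = as.numeric(mf$intercept)),
              class = "plsr_model")
  } else {
    structure(list(alpha = as.numeric(mf$alpha),
                   bias = as.numeric(mf$bias),
                   gamma = as.numeric(mf$gamma),
                   sigma2 = as.numeric(mf$sigma2),
                   X_train = as_mat(mf$X_train)),
              class = "lssvm_model")
  }
  metrics <- obj$metrics
  metrics$rpd <- if (identical(metrics$rpd, "Inf")) Inf else
    as.numeric(metrics$rpd)
  structure(list(model = model, method = obj$method,
                 hyperparams = as.list(obj$hyperparams),
                 preprocess = preprocess_spec(obj$preprocess),
                 selection = new_selection_result(obj$selection$method,
                                                 obj$selection$selected),
                 wavelengths = as.numeric(obj$wavelengths),
                 scale = obj$scale, target = obj$target,
                 label = obj$label,
                 metrics = structure(metrics, class = "metrics_report"),
                 version = obj$version),
            class = "model_bundle")
}
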