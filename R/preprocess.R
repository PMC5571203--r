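#' Standard normal variate transform
#'
#' Centers and scales one spectrum to mean 0 and sample standard deviation
#' 1 (n-1 denominator), removing per-spectrum multiplicative scatter and
#' additive offset.
#'
#' @param x numeric spectrum of length >= 2, not constant.
#' @return Transformed spectrum.
#' @export
snv <- function(x) {
  pm_check(is.numeric(x) && length(x) >= 2, "spectrum must have length >= 2")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    pm_stop("constant spectrum: SNV undefined", "degenerate_spectrum")
  (x - mean(x)) / s
}

#' Savitzky-Golay smoothing
#'
#' Sliding-window local least-squares polynomial fit evaluated at the window
#' centre.  The first and last \code{(window-1)/2} points are produced by
#' evaluating the terminal windows' polynomial fits at the off-centre
#' positions, so a polynomial of degree <= \code{poly_order} is reproduced
#' exactly everywhere including the edges.
#'
#' @param x numeric spectrum, length >= \code{window}.
#' @param window odd window length, \code{window > poly_order}.
#' @param poly_order polynomial degree (>= 0).
#' @return Smoothed spectrum of the same length.
#' @export
savitzky_golay <- function(x, window = 7L, poly_order = 2L) {
  pm_check(is.numeric(x), "x must be numeric")
  if (window %% 2 == 0 || window <= poly_order || poly_order < 0)
    pm_stop("window must be odd and greater than poly_order",
            "invalid_argument")
  n <- length(x)
  pm_check(window <= n, "window longer than the spectrum")
  h <- (window - 1L) %/% 2L
  V <- outer(-h:h, 0:poly_order, `^`)            # window Vandermonde
  H <- V %*% solve(crossprod(V), t(V))           # projection (hat) matrix
  out <- numeric(n)
  centre <- H[h + 1L, ]
  # centre weights are symmetric (smoothing, not derivative), so plain
  # two-sided convolution applies them correctly and vectorizes the interior
  interior <- stats::filter(x, centre, sides = 2)
  out[(h + 1L):(n - h)] <- interior[(h + 1L):(n - h)]
  head_fit <- H %*% x[1:window]
  out[1:h] <- head_fit[1:h]
  tail_fit <- H %*% x[(n - window + 1L):n]
  out[(n - h + 1L):n] <- tail_fit[(window - h + 1L):window]
  out
}

#' Preprocessing specification
#'
#' Ordered list of per-spectrum pretreatment steps.  Steps are given as
#' strings: \code{"none"}, \code{"snv"}, or \code{"sg:<window>:<order>"}
#' (e.g. \code{"sg:7:2"}).  Order is preserved; the pipeline default for a
#' "with preprocessing" arm is Savitzky-Golay smoothing followed by SNV.
#'
#' @param steps character vector of step strings.
#' @return Object of class \code{"preprocess_spec"}.
#' @examples
#' preprocess_spec(c("sg:7:2", "snv"))
#' @export
preprocess_spec <- function(steps = "none") {
  pm_check(is.character(steps) && length(steps) >= 1,
           "steps must be a character vector")
  parsed <- lapply(steps, function(s) {
    if (s == "none") return(list(kind = "none"))
    if (s == "snv") return(list(kind = "snv"))
    if (grepl("^sg:\\d+:\\d+$", s)) {
      parts <- as.integer(strsplit(s, ":")[[1L]][2:3])
      if (parts[1L] %% 2 == 0 || parts[1L] <= parts[2L])
        pm_stop("sg window must be odd and > poly order", "invalid_argument")
      return(list(kind = "sg", window = parts[1L], poly_order = parts[2L]))
    }
    pm_stop(sprintf("unknown preprocessing step '%s'", s), "invalid_argument")
  })
  structure(list(steps = parsed, labels = steps), class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess_spec>", paste(x$labels, collapse = " -> "), "\n")
  invisible(x)
}

apply_steps <- function(x, spec) {
  for (st in spec$steps) {
    x <- switch(st$kind,
                none = x,
                snv = snv(x),
                sg = savitzky_golay(x, st$window, st$poly_order))
  }
  x
}

#' Apply a preprocessing spec to a spectra matrix
#'
#' Each row (spectrum) is transformed independently by the ordered steps;
#' the \code{"none"} spec returns the input unchanged.  Row-level errors are
#' re-raised with the offending row index.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param spec a [preprocess_spec()] (or character vector coerced to one).
#' @return Transformed matrix of the same shape.
#' @export
preprocess_matrix <- function(X, spec = preprocess_spec("none")) {
  if (is.character(spec)) spec <- preprocess_spec(spec)
  pm_check(is.matrix(X) && is.numeric(X), "X must be a numeric matrix")
  if (length(spec$steps) == 1L && spec$steps[[1L]]$kind == "none") return(X)
  out <- X
  for (i in seq_len(nrow(X))) {
    out[i, ] <- tryCatch(apply_steps(X[i, ], spec), pectinmap_error =
      function(e) pm_stop(sprintf("row %d: %s", i, conditionMessage(e)),
                          sub("^pectinmap_", "", class(e)[1L])))
  }
  out
}
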