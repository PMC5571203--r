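#' Fit a PLSR model (NIPALS)
#'
#' Univariate partial least squares regression by sequential NIPALS
#' extraction with deflation.  Predictors and response are mean-centred
#' internally (no autoscaling: row scale is the preprocessing stage's job);
#' regression coefficients are mapped back to the original band space for
#' every component count 1..\code{n_latent}, which lets cross-validation and
#' the coefficient-based selectors (UVE, CARS) reuse one fit.
#'
#' Extraction stops early if the residual covariance with y vanishes
#' numerically (rank-deficient X), in which case the achieved number of
#' components is recorded in \code{n_latent}.
#'
#' @param X numeric matrix n x p of predictor spectra.
#' @param y numeric response vector (mg/g), non-constant.
#' @param n_latent requested number of latent components,
#'   \code{1 <= n_latent <= min(n - 1, p)}.
#' @return Object of class \code{"plsr_model"} with elements
#'   \code{n_latent}, \code{x_mean}, \code{y_mean}, \code{weights},
#'   \code{x_loadings}, \code{y_loadings}, \code{scores},
#'   \code{coef_path} (p x n_latent matrix of coefficients per component
#'   count), \code{coefficients}, \code{intercept}.
#' @export
fit_plsr <- function(X, y, n_latent) {
  pm_check(is.matrix(X) && is.numeric(X), "X must be a numeric matrix")
  n <- nrow(X); p <- ncol(X)
  pm_check(length(y) == n && n >= 2, "X and y sizes incompatible (n >= 2)")
  if (stats::sd(y) == 0)
    pm_stop("response has zero variance", "degenerate_target")
  amax <- min(n - 1L, p)
  if (!is_scalar_number(n_latent) || n_latent < 1 || n_latent > amax)
    pm_stop(sprintf("n_latent must lie in 1..%d", amax), "invalid_argument")
  n_latent <- as.integer(n_latent)
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean); f <- y - y_mean
  W <- matrix(0, p, n_latent); P <- matrix(0, p, n_latent)
  Q <- numeric(n_latent); TT <- matrix(0, n, n_latent)
  # stop extraction only when the residual covariance or score norm falls
  # to the float-noise floor relative to the first component (genuinely
  # small components carry real signal on noiseless synthetic data)
  a <- 0L
  wn1 <- NA_real_; tt1 <- NA_real_
  for (k in seq_len(n_latent)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn == 0) break
    if (is.na(wn1)) wn1 <- wn else if (wn <= 1e-14 * wn1) break
    w <- w / wn
    t_ <- as.numeric(E %*% w)
    tt <- sum(t_^2)
    if (!is.finite(tt) || tt == 0) break
    if (is.na(tt1)) tt1 <- tt else if (tt <= 1e-28 * tt1) break
    p_ <- as.numeric(crossprod(E, t_)) / tt
    q_ <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
    a <- k
    W[, k] <- w; P[, k] <- p_; Q[k] <- q_; TT[, k] <- t_
  }
  pm_check(a >= 1, "no latent component could be extracted",
           class = "degenerate_target")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[seq_len(a)]; TT <- TT[, seq_len(a), drop = FALSE]
  # R = W (P'W)^-1 maps X (centred) to scores; coefficients per component
  # count via cumulative sums of R_a Q_a.
  R <- W %*% backsolve(crossprod(P, W), diag(a), upper.tri = TRUE)
  coef_path <- sapply(seq_len(a), function(k)
    as.numeric(R[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)]))
  coef_path <- matrix(coef_path, p, a)
  b <- coef_path[, a]
  structure(list(n_latent = a, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = Q, scores = TT,
                 coef_path = coef_path, coefficients = b,
                 intercept = y_mean - sum(x_mean * b)),
            class = "plsr_model")
}

#' Predict from a PLSR model
#'
#' @param object a [fit_plsr()] model.
#' @param newdata numeric matrix (rows = spectra) or a single spectrum
#'   vector with the model's band count.
#' @param n_latent component count to use (default: the fitted maximum).
#' @param via \code{"coefficients"} (default) or \code{"scores"}: the score
#'   recursion computes predictions component by component and must agree
#'   with the coefficient path to numerical precision.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, n_latent = object$n_latent,
                               via = c("coefficients", "scores"), ...) {
  via <- match.arg(via)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$x_mean))
    pm_stop("band count of newdata does not match the model",
            "invalid_argument")
  pm_check(n_latent >= 1 && n_latent <= object$n_latent,
           "n_latent outside the fitted range")
  E <- sweep(newdata, 2L, object$x_mean)
  if (via == "coefficients") {
    b <- object$coef_path[, n_latent]
    return(object$y_mean + as.numeric(E %*% b))
  }
  yhat <- rep(object$y_mean, nrow(newdata))
  for (k in seq_len(n_latent)) {
    t_ <- as.numeric(E %*% object$weights[, k])
    yhat <- yhat + object$y_loadings[k] * t_
    E <- E - tcrossprod(t_, object$x_loadings[, k])
  }
  yhat
}
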