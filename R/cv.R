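#' Full leave-one-out cross-validation
#'
#' Performs n explicit refits, each omitting one sample; the i-th
#' cross-validated prediction comes from the model trained without sample i.
#' No hat-matrix shortcut is used for the model families themselves, so the
#' same code path serves PLSR and LS-SVM.
#'
#' @param X numeric matrix n x p (n >= 3).
#' @param y numeric response vector.
#' @param method \code{"plsr"} or \code{"lssvm"}.
#' @param n_latent PLSR component count.
#' @param gamma,sigma2 LS-SVM hyperparameters.
#' @return List with \code{cv_predictions} (length n) and \code{rmsecv}.
#' @export
loo_cv <- function(X, y, method = c("plsr", "lssvm"), n_latent = NULL,
                   gamma = NULL, sigma2 = NULL) {
  method <- match.arg(method)
  n <- nrow(X)
  pm_check(n >= 3, "leave-one-out needs at least 3 samples")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch({
      if (method == "plsr") {
        m <- fit_plsr(X[-i, , drop = FALSE], y[-i],
                      min(n_latent, n - 2L, ncol(X)))
      } else {
        m <- fit_lssvm(X[-i, , drop = FALSE], y[-i], gamma, sigma2)
      }
      m
    }, pectinmap_error = function(e)
      pm_stop(sprintf("fold %d: %s", i, conditionMessage(e)),
              sub("^pectinmap_", "", class(e)[1L])))
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  list(cv_predictions = pred, rmsecv = rmse(y, pred))
}

# LOO predictions for every PLSR component count 1..a_max in one pass:
# each fold is still an explicit refit, but the nested NIPALS coefficient
# path prices all component counts at once.  Returns n x a matrix (a =
# minimum achieved component count across folds).
loo_plsr_path <- function(X, y, a_max) {
  n <- nrow(X)
  pm_check(n >= 3, "leave-one-out needs at least 3 samples")
  a_max <- min(a_max, n - 2L, ncol(X))
  preds <- vector("list", n)
  a_min <- Inf
  for (i in seq_len(n)) {
    m <- fit_plsr(X[-i, , drop = FALSE], y[-i], a_max)
    a_min <- min(a_min, m$n_latent)
    E <- X[i, ] - m$x_mean
    preds[[i]] <- m$y_mean + as.numeric(E %*% m$coef_path)
  }
  a_min <- as.integer(a_min)
  out <- t(vapply(preds, function(p) p[seq_len(a_min)], numeric(a_min)))
  matrix(out, n, a_min)
}

#' Hyperparameter tuning by leave-one-out RMSECV
#'
#' PLSR: the component count in \code{1..min(20, n-1)} minimizing RMSECV
#' (ties broken toward fewer components).  LS-SVM: exhaustive search of a
#' log10 grid \code{10^-1..10^6 x 10^-1..10^6} for (gamma, sigma2), ties
#' broken toward smaller gamma then smaller sigma2.  The same LOO split
#' serves tuning and final evaluation (reported RMSECV is the winning grid
#' point's), a deliberately non-nested protocol whose optimistic bias is
#' discussed in the package vignette.
#'
#' @param X numeric matrix n x p.
#' @param y numeric response vector.
#' @param method \code{"plsr"} or \code{"lssvm"}.
#' @param n_latent_max PLSR search upper bound (default \code{min(20, n-1)}).
#' @param gamma_grid,sigma2_grid LS-SVM search grids (default log10 decades
#'   from 1e-1 to 1e6).
#' @return List with \code{hyperparams} (named list), \code{rmsecv},
#'   \code{cv_predictions}, and \code{trace} (data.frame of every candidate
#'   and its RMSECV).
#' @export
tune_hyperparameters <- function(X, y, method = c("plsr", "lssvm"),
                                 n_latent_max = NULL,
                                 gamma_grid = 10^seq(-1, 6),
                                 sigma2_grid = 10^seq(-1, 6)) {
  method <- match.arg(method)
  n <- nrow(X)
  if (method == "plsr") {
    if (is.null(n_latent_max)) n_latent_max <- min(20L, n - 1L)
    pm_check(n_latent_max >= 1, "empty search space")
    P <- loo_plsr_path(X, y, n_latent_max)
    rms <- apply(P, 2L, function(p) rmse(y, p))
    # near-ties (within float precision of the minimum) resolve toward the
    # simplest model
    best <- which(rms <= min(rms) * (1 + 1e-8) + 1e-15)[1L]
    return(list(hyperparams = list(n_latent = as.integer(best)),
                rmsecv = rms[best],
                cv_predictions = P[, best],
                trace = data.frame(n_latent = seq_along(rms), rmsecv = rms)))
  }
  pm_check(length(gamma_grid) >= 1 && length(sigma2_grid) >= 1,
           "empty search space")
  grid <- expand.grid(sigma2 = sort(sigma2_grid), gamma = sort(gamma_grid))
  grid <- grid[order(grid$gamma, grid$sigma2), , drop = FALSE]
  rms <- numeric(nrow(grid))
  preds <- vector("list", nrow(grid))
  an <- rowSums(X^2)
  D2 <- outer(an, an, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  for (g in seq_len(nrow(grid))) {
    K <- exp(-D2 / grid$sigma2[g])
    pred <- numeric(n)
    for (i in seq_len(n)) {
      Ki <- K[-i, -i, drop = FALSE]
      A <- rbind(c(0, rep(1, n - 1L)),
                 cbind(rep(1, n - 1L), Ki + diag(n - 1L) / grid$gamma[g]))
      sol <- tryCatch(solve(A, c(0, y[-i])), error = function(e) NULL)
      if (is.null(sol)) { pred <- rep(Inf, n); break }
      pred[i] <- sum(K[i, -i] * sol[-1L]) + sol[1L]
    }
    preds[[g]] <- pred
    rms[g] <- if (all(is.finite(pred))) rmse(y, pred) else Inf
  }
  best <- which(rms <= min(rms) * (1 + 1e-8) + 1e-15)[1L]
  list(hyperparams = list(gamma = grid$gamma[best],
                          sigma2 = grid$sigma2[best]),
       rmsecv = rms[best],
       cv_predictions = preds[[best]],
       trace = cbind(grid, rmsecv = rms))
}
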