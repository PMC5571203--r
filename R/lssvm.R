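#' Fit an LS-SVM regression model (RBF kernel)
#'
#' Least squares support vector machine regression: the dual coefficients
#' alpha and bias b solve the saddle-point linear (KKT) system
#' \deqn{\begin{pmatrix} 0 & 1^T \\ 1 & K + I/\gamma \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix},}
#' with the RBF kernel \eqn{K_{ij} = \exp(-\|x_i - x_j\|^2 / \sigma^2)}.
#' Note the squared-distance / sigma-squared convention: \code{sigma2}
#' divides the squared Euclidean distance directly.
#'
#' @param X numeric matrix n x p of training spectra (stored in the model).
#' @param y numeric response vector.
#' @param gamma regularization parameter (> 0); larger = less regularized.
#' @param sigma2 RBF bandwidth on the squared-distance scale (> 0).
#' @return Object of class \code{"lssvm_model"} with \code{alpha},
#'   \code{bias}, \code{gamma}, \code{sigma2}, \code{X_train} and the KKT
#'   residual norm \code{kkt_residual}.
#' @export
fit_lssvm <- function(X, y, gamma, sigma2) {
  pm_check(is.matrix(X) && is.numeric(X), "X must be a numeric matrix")
  n <- nrow(X)
  pm_check(length(y) == n && n >= 2, "X and y sizes incompatible")
  pm_check(is_scalar_number(gamma) && gamma > 0, "gamma must be > 0")
  pm_check(is_scalar_number(sigma2) && sigma2 > 0, "sigma2 must be > 0")
  K <- rbf_kernel(X, X, sigma2)
  A <- rbind(c(0, rep(1, n)), cbind(rep(1, n), K + diag(n) / gamma))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    pm_stop(sprintf("singular KKT system (rcond ~ %.3e): %s",
                    rcond(A), conditionMessage(e)), "numerical_failure"))
  res <- max(abs(A %*% sol - rhs))
  structure(list(alpha = sol[-1L], bias = sol[1L], gamma = gamma,
                 sigma2 = sigma2, X_train = X, kkt_residual = res),
            class = "lssvm_model")
}

# Pairwise-squared-distance RBF kernel between row sets.
rbf_kernel <- function(A, B, sigma2) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

#' Predict from an LS-SVM model
#'
#' @param object a [fit_lssvm()] model.
#' @param newdata matrix of spectra (or a single spectrum vector).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != ncol(object$X_train))
    pm_stop("band count of newdata does not match the model",
            "invalid_argument")
  K <- rbf_kernel(newdata, object$X_train, object$sigma2)
  as.numeric(K %*% object$alpha) + object$bias
}
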