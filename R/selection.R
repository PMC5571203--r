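new_selection_result <- function(method, selected, diagnostics = list()) {
  selected <- sort(unique(as.integer(selected)))
  pm_check(length(selected) >= 1, "empty selection", class = "empty_selection")
  structure(list(method = method, selected = selected,
                 diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d bands\n", x$method,
              length(x$selected)))
  invisible(x)
}

# Exact leave-one-out RMSE of ordinary multiple linear regression with
# intercept via the PRESS identity e_i / (1 - h_ii); algebraically equal to
# n explicit refits.
mlr_loo_rmse <- function(Xs, y) {
  Z <- cbind(1, Xs)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) return(Inf)
  e <- qr.resid(qz, y)
  h <- rowSums(qr.Q(qz)[, seq_len(qz$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-10)) return(Inf)
  sqrt(mean((e / (1 - h))^2))
}

# Greedy projection chain of SPA from one start column: repeatedly add the
# column with the largest residual norm after projection onto the orthogonal
# complement of the span of the chain.
spa_chain <- function(X, start, k_max, tol) {
  p <- ncol(X)
  chain <- integer(0L)
  Rm <- X
  cur <- start
  for (step in seq_len(k_max)) {
    chain <- c(chain, cur)
    u <- Rm[, cur]
    uu <- sum(u^2)
    if (uu <= tol) { chain <- chain[-length(chain)]; break }
    Rm <- Rm - u %*% (crossprod(u, Rm) / uu)
    if (length(chain) == k_max) break
    norms <- colSums(Rm^2)
    norms[chain] <- -1
    if (max(norms) <= tol) break
    cur <- which.max(norms)          # first index wins ties
  }
  chain
}

#' Wavelength selection by the successive projections algorithm (SPA)
#'
#' Forward selection minimizing collinearity: from every candidate start
#' column a chain is grown by repeatedly adding the column with the largest
#' norm after projection onto the orthogonal complement of the chain's
#' span.  Every candidate set (chain prefix of length k, k in
#' \code{k_min..k_max}) is scored by the leave-one-out RMSE of a multiple
#' linear regression on those columns, and the minimizing set is returned
#' (ties: fewer bands, then smaller start index).  Duplicated columns can
#' never co-occur in a chain because the projection of a duplicate is the
#' zero vector.
#'
#' @param X numeric matrix n x p of (preprocessed) spectra.
#' @param y numeric response.
#' @param k_min,k_max candidate set size range,
#'   \code{1 <= k_min <= k_max <= min(n - 1, p)}.
#' @param starts candidate start columns (default: all).
#' @return A \code{selection_result}; diagnostics hold the per-(start, k)
#'   RMSE curve and the chain of the winning start.
#' @export
spa_select <- function(X, y, k_min = 1L, k_max = NULL,
                       starts = seq_len(ncol(X))) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(k_max)) k_max <- min(20L, n - 2L, p)
  if (k_min < 1 || k_max < k_min || k_max > min(n - 1L, p))
    pm_stop("k range infeasible for this matrix", "invalid_argument")
  tol <- 1e-10 * max(colSums(X^2))
  best <- list(rmse = Inf, k = Inf, start = Inf, set = NULL)
  curve <- list()
  chains <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    s <- starts[si]
    chain <- spa_chain(X, s, k_max, tol)
    chains[[si]] <- chain
    if (length(chain) < k_min) next
    for (k in seq.int(k_min, length(chain))) {
      set <- chain[seq_len(k)]
      r <- mlr_loo_rmse(X[, set, drop = FALSE], y)
      curve[[length(curve) + 1L]] <- data.frame(start = s, k = k, rmse = r)
      better <- isTRUE(r < best$rmse - 1e-15) ||
        (is.finite(r) && isTRUE(abs(r - best$rmse) <= 1e-15) &&
           (k < best$k || (k == best$k && s < best$start)))
      if (better) best <- list(rmse = r, k = k, start = s, set = set)
    }
  }
  pm_check(!is.null(best$set), "no scorable SPA candidate set",
           class = "empty_selection")
  new_selection_result("spa", best$set, list(
    rmse_curve = do.call(rbind, curve),
    chain_starts = starts,
    winning_start = best$start,
    winning_chain = chains[[match(best$start, starts)]],
    rmse = best$rmse))
}

#' Uninformative variable elimination (UVE)
#'
#' Appends \code{noise_count} artificial noise columns (uniform noise scaled
#' to 1e-10 of the spectral magnitude), runs a leave-one-out jackknife of
#' PLSR collecting the per-fold coefficient vectors, and computes for each
#' variable the stability \eqn{c_j = mean_folds(b_j) / sd_folds(b_j)}.  The
#' cutoff is \code{cutoff_factor} times the largest |c| among the noise
#' columns; real variables with |c| above the cutoff are retained.  By
#' construction no injected noise column survives its own cutoff at
#' \code{cutoff_factor = 1}.
#'
#' @param X numeric matrix n x p.
#' @param y numeric response.
#' @param n_latent PLSR components for the jackknife (default
#'   \code{min(10, n - 2)}).
#' @param noise_count number of artificial columns (default p).
#' @param cutoff_factor multiplier on the noise stability maximum.
#' @param seed RNG seed for the noise columns.
#' @return A \code{selection_result}; diagnostics hold the stability values
#'   of real and noise variables and the cutoff.
#' @export
uve_select <- function(X, y, n_latent = NULL, noise_count = ncol(X),
                       cutoff_factor = 1, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(n_latent)) n_latent <- min(10L, n - 2L)
  pm_check(n_latent >= 1 && n_latent <= min(n - 2L, p + noise_count),
           "n_latent invalid for the jackknife")
  scale_ <- 1e-10 * max(abs(X))
  noise <- withr::with_seed(seed,
    matrix(stats::runif(n * noise_count), n, noise_count)) * scale_
  Xa <- cbind(X, noise)
  B <- matrix(NA_real_, n, p + noise_count)
  for (i in seq_len(n)) {
    m <- fit_plsr(Xa[-i, , drop = FALSE], y[-i],
                  min(n_latent, n - 2L, ncol(Xa)))
    B[i, ] <- m$coef_path[, m$n_latent]
  }
  mu <- colMeans(B); sdv <- apply(B, 2L, stats::sd)
  c_all <- mu / sdv
  c_all[!is.finite(c_all) & abs(mu) < .Machine$double.eps] <- 0
  c_real <- c_all[seq_len(p)]
  c_noise <- c_all[p + seq_len(noise_count)]
  cutoff <- cutoff_factor * max(abs(c_noise))
  keep <- which(abs(c_real) > cutoff)
  if (length(keep) == 0L)
    pm_stop(sprintf(
      "UVE eliminated all variables (cutoff %.4g, max real |c| %.4g)",
      cutoff, max(abs(c_real))), "empty_selection")
  new_selection_result("uve", keep, list(
    stability_real = c_real, stability_noise = c_noise, cutoff = cutoff))
}

#' UVE-SPA cascade
#'
#' Runs [uve_select()] first, then [spa_select()] restricted to the
#' surviving columns; the result is always a subset of the UVE survivors and
#' the diagnostics of both stages are kept.
#'
#' @inheritParams uve_select
#' @param k_min,k_max forwarded to the SPA stage.
#' @return A \code{selection_result} with method \code{"uve_spa"}.
#' @export
uve_spa_select <- function(X, y, n_latent = NULL, noise_count = ncol(X),
                           cutoff_factor = 1, k_min = 1L, k_max = NULL,
                           seed = 1L) {
  uve <- uve_select(X, y, n_latent = n_latent, noise_count = noise_count,
                    cutoff_factor = cutoff_factor, seed = seed)
  sub <- uve$selected
  if (is.null(k_max)) k_max <- min(20L, nrow(X) - 2L, length(sub))
  k_max <- min(k_max, length(sub))
  k_min <- min(k_min, k_max)
  spa <- spa_select(X[, sub, drop = FALSE], y, k_min = k_min, k_max = k_max)
  new_selection_result("uve_spa", sub[spa$selected], list(
    uve = uve$diagnostics, spa = spa$diagnostics, uve_survivors = sub))
}

#' CARS exponentially decreasing retention schedule
#'
#' Retention ratios \eqn{r_i = a e^{-k i}} with
#' \eqn{a = (p/2)^{1/(N-1)}} and \eqn{k = \ln(p/2)/(N-1)}, so that
#' \eqn{r_1 = 1} (all p bands retained at the start) and
#' \eqn{r_N = 2/p} (two bands at the end).
#'
#' @param p number of bands.
#' @param n_runs number of Monte-Carlo runs N.
#' @return Numeric vector \code{r_1..r_N}.
#' @export
cars_ratio_schedule <- function(p, n_runs) {
  pm_check(n_runs >= 2 && p >= 2, "need n_runs >= 2 and p >= 2")
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * seq_len(n_runs))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' At run i of N, a PLSR model is fitted on a random \code{mc_fraction}
#' subset of the samples using the currently retained bands; bands are
#' weighted by their normalized absolute regression coefficients; the
#' enforced exponentially decreasing schedule keeps the top
#' \code{ceiling(r_i * p)} bands by weight, and adaptive reweighted sampling
#' (weighted sampling with replacement, deduplicated) is applied among
#' them.  Each run's subset is scored by the LOO RMSECV of PLSR on the full
#' sample set, and the run with minimal RMSECV wins (ties: earlier run).  If
#' the retained set falls below 2 bands the loop stops early and the best
#' run so far is returned.
#'
#' @param X numeric matrix n x p.
#' @param y numeric response.
#' @param n_runs number of Monte-Carlo runs (>= 2), default 50.
#' @param n_latent_max PLSR component cap, default 10.
#' @param mc_fraction Monte-Carlo sample fraction in (0, 1), default 0.8.
#' @param seed RNG seed for the Monte-Carlo subsets and the reweighted
#'   sampling.
#' @return A \code{selection_result}; diagnostics hold the schedule counts
#'   \code{ceiling(r_i * p)}, the per-run retained counts and RMSECVs, and
#'   the winning run index.
#' @export
cars_select <- function(X, y, n_runs = 50L, n_latent_max = 10L,
                        mc_fraction = 0.8, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  pm_check(n_runs >= 2, "n_runs must be >= 2")
  pm_check(mc_fraction > 0 && mc_fraction < 1,
           "mc_fraction must be in (0, 1)")
  r <- cars_ratio_schedule(p, n_runs)
  schedule_counts <- as.integer(ceiling(r * p))
  nsub <- max(2L, ceiling(mc_fraction * n))
  retained <- seq_len(p)
  subsets <- vector("list", n_runs)
  rmsecv <- rep(NA_real_, n_runs)
  actual_counts <- rep(NA_integer_, n_runs)
  runs_done <- 0L
  withr::with_seed(seed, {
    for (i in seq_len(n_runs)) {
      sub <- sample.int(n, nsub)
      a <- min(n_latent_max, nsub - 2L, length(retained))
      m <- fit_plsr(X[sub, retained, drop = FALSE], y[sub], max(1L, a))
      w <- abs(m$coef_path[, m$n_latent])
      w <- w / sum(w)
      keep_n <- min(schedule_counts[i], length(retained))
      ord <- order(-w, seq_along(w))
      top <- ord[seq_len(keep_n)]
      # adaptive reweighted sampling among the survivors
      draw <- sample(top, size = keep_n, replace = TRUE, prob = w[top])
      retained <- sort(retained[unique(draw)])
      subsets[[i]] <- retained
      actual_counts[i] <- length(retained)
      path <- loo_plsr_path(X[, retained, drop = FALSE], y,
                            min(n_latent_max, n - 2L, length(retained)))
      rmsecv[i] <- min(apply(path, 2L, function(pr) rmse(y, pr)))
      runs_done <- i
      if (length(retained) < 2L) break
    }
  })
  best <- which.min(rmsecv[seq_len(runs_done)])
  new_selection_result("cars", subsets[[best]], list(
    schedule_counts = schedule_counts,
    retained_counts = actual_counts[seq_len(runs_done)],
    rmsecv = rmsecv[seq_len(runs_done)],
    winning_run = best,
    runs_done = runs_done))
}

#' Full-spectrum (no selection)
#'
#' @param n_bands number of bands (>= 1).
#' @return A \code{selection_result} selecting every band.
#' @export
full_selection <- function(n_bands) {
  pm_check(n_bands >= 1, "n_bands must be >= 1")
  new_selection_result("full", seq_len(n_bands))
}

#' Export a selection as a two-column CSV (index, nm)
#'
#' @param result a \code{selection_result}.
#' @param wavelengths wavelength axis (nm) the indices refer to.
#' @param path CSV path.
#' @export
write_selection_csv <- function(result, wavelengths, path) {
  utils::write.csv(data.frame(index = result$selected,
                              wavelength_nm = wavelengths[result$selected]),
                   path, row.names = FALSE)
  invisible(path)
}
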