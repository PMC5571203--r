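# Independent SPA oracle: greedy chains via explicit QR projections and
# candidate scoring by explicit leave-one-out refits of lm().  Kept fully
# separate from the package's deflation-based implementation.
oracle_spa <- function(X, y, k_min, k_max) {
  n <- nrow(X); p <- ncol(X)
  chain_of <- function(start) {
    chain <- start
    while (length(chain) < k_max) {
      Q <- qr.Q(qr(X[, chain, drop = FALSE]))
      resid_norm <- vapply(seq_len(p), function(j) {
        if (j %in% chain) return(-1)
        r <- X[, j] - Q %*% crossprod(Q, X[, j])
        sum(r^2)
      }, numeric(1))
      if (max(resid_norm) <= 1e-10 * max(colSums(X^2))) break
      chain <- c(chain, which.max(resid_norm))
    }
    chain
  }
  loo_rmse <- function(set) {
    pr <- vapply(seq_len(n), function(i) {
      df <- data.frame(y = y[-i], X[-i, set, drop = FALSE])
      fit <- lm(y ~ ., data = df)
      nd <- data.frame(X[i, set, drop = FALSE])
      names(nd) <- names(df)[-1]
      unname(predict(fit, nd))
    }, numeric(1))
    sqrt(mean((y - pr)^2))
  }
  best <- list(rmse = Inf, k = Inf, start = Inf, set = NULL)
  for (s in seq_len(p)) {
    ch <- chain_of(s)
    for (k in k_min:min(k_max, length(ch))) {
      r <- loo_rmse(ch[seq_len(k)])
      if (r < best$rmse - 1e-12 ||
          (abs(r - best$rmse) <= 1e-12 &&
             (k < best$k || (k == best$k && s < best$start))))
        best <- list(rmse = r, k = k, start = s, set = sort(ch[seq_len(k)]))
    }
  }
  best
}
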