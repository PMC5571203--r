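test_that("PLSR fits exact univariate relationships", {
  x <- matrix(seq(1, 10), ncol = 1)
  y <- 2 * as.numeric(x)
  m <- fit_plsr(x, y, 1)
  expect_lt(sqrt(mean((y - predict(m, x))^2)), 1e-10)
  expect_error(fit_plsr(x, rep(1, 10), 1),
               class = "pectinmap_degenerate_target")
  expect_error(fit_plsr(x, y, 5), class = "pectinmap_invalid_argument")
})

test_that("PLSR with maximal components equals OLS on full-rank data", {
  toy <- toy_regression(10, 5)
  m <- fit_plsr(toy$X, toy$y, 5)
  ols <- lm.fit(cbind(1, toy$X), toy$y)   # normal-equations oracle
  expect_equal(predict(m, toy$X), unname(ols$fitted.values),
               tolerance = 1e-8)
})

test_that("NIPALS scores are mutually orthogonal", {
  toy <- toy_regression(20, 8, seed = 9)
  m <- fit_plsr(toy$X, toy$y, 6)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-10)
})

test_that("PLSR coefficient and score-recursion predictions agree", {
  toy <- toy_regression(15, 12, seed = 4)
  m <- fit_plsr(toy$X, toy$y, 5)
  Xn <- withr::with_seed(5, matrix(rnorm(6 * 12), 6, 12))
  for (a in 1:5) {
    expect_equal(predict(m, Xn, n_latent = a, via = "coefficients"),
                 predict(m, Xn, n_latent = a, via = "scores"),
                 tolerance = 1e-10)
  }
})

test_that("LS-SVM satisfies its KKT system and near-interpolates", {
  toy <- toy_regression(12, 3, seed = 8)
  m <- fit_lssvm(toy$X, toy$y, gamma = 10, sigma2 = 5)
  expect_lt(m$kkt_residual, 1e-8)
  # independent linear-solver check of the saddle-point system
  n <- 12
  K <- exp(-as.matrix(dist(toy$X))^2 / 5)
  A <- rbind(c(0, rep(1, n)), cbind(rep(1, n), K + diag(n) / 10))
  sol <- c(m$bias, m$alpha)
  expect_lt(max(abs(A %*% sol - c(0, toy$y))), 1e-8)
  # large gamma limit: training residuals vanish
  X5 <- matrix(seq_len(5), ncol = 1)
  y5 <- c(1.2, -0.4, 2.2, 0.1, 1.8)
  m2 <- fit_lssvm(X5, y5, gamma = 1e8, sigma2 = 4)
  expect_lt(max(abs(y5 - predict(m2, X5))), 1e-3)
  expect_error(fit_lssvm(X5, y5, -1, 1),
               class = "pectinmap_invalid_argument")
})

test_that("LS-SVM handles duplicated training points with equal response", {
  X <- matrix(c(1, 1, 2, 3), ncol = 1)
  y <- c(0.5, 0.5, 1.1, 2.0)
  m <- fit_lssvm(X, y, gamma = 10, sigma2 = 2)
  expect_equal(predict(m, matrix(1)), 0.5, tolerance = 0.2)
})

test_that("batch prediction equals row-by-row prediction", {
  toy <- toy_regression(10, 4, seed = 2)
  for (m in list(fit_plsr(toy$X, toy$y, 3),
                 fit_lssvm(toy$X, toy$y, 100, 10))) {
    batch <- predict(m, toy$X)
    single <- vapply(seq_len(10), function(i)
      predict(m, toy$X[i, , drop = FALSE]), numeric(1))
    expect_equal(batch, single, tolerance = 1e-12)
    expect_error(predict(m, matrix(0, 2, 7)),
                 class = "pectinmap_invalid_argument")
  }
})

test_that("LOO-CV equals manually assembled refits", {
  toy <- toy_regression(5, 3, seed = 31)
  got <- loo_cv(toy$X, toy$y, "plsr", n_latent = 2)
  manual <- vapply(1:5, function(i) {
    m <- fit_plsr(toy$X[-i, ], toy$y[-i], 2)
    predict(m, toy$X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(got$cv_predictions, manual, tolerance = 1e-12)
  expect_equal(got$rmsecv, sqrt(mean((toy$y - manual)^2)),
               tolerance = 1e-12)
  # degenerate target surfaces through the fold error
  err <- tryCatch(loo_cv(toy$X, rep(1, 5), "plsr", n_latent = 1),
                  error = identity)
  expect_s3_class(err, "pectinmap_degenerate_target")
  expect_match(conditionMessage(err), "fold")
})

test_that("duplicating every sample strictly shrinks the LOO RMSECV", {
  cfg <- tiny_noisy_config(n_slices = 10, bands = 16, px = 12, seed = 17)
  st <- scene_table(cfg)
  X <- st$table$X; y <- st$table$y$protopectin
  base <- loo_cv(X, y, "plsr", n_latent = 4)$rmsecv
  dup <- loo_cv(X[rep(1:10, 2), ], rep(y, 2), "plsr", n_latent = 4)$rmsecv
  expect_lt(dup, base)
})

test_that("hyperparameter tuning minimizes RMSECV over its grid", {
  # exact linear response living in a 3-dimensional predictor subspace
  withr::with_seed(6, {
    T3 <- matrix(rnorm(20 * 3), 20, 3)
    X <- T3 %*% matrix(rnorm(3 * 6), 3, 6)
    y <- as.numeric(T3 %*% c(1, -2, 0.5))
  })
  tu <- tune_hyperparameters(X, y, "plsr")
  expect_lte(tu$hyperparams$n_latent, 3)
  expect_lt(tu$rmsecv, 1e-8)
  # grid of one point returns that point
  toy <- toy_regression(8, 3, seed = 13)
  tu1 <- tune_hyperparameters(toy$X, toy$y, "lssvm",
                              gamma_grid = 10, sigma2_grid = 2)
  expect_identical(tu1$hyperparams, list(gamma = 10, sigma2 = 2))
  # exhaustive-grid oracle: the chosen LS-SVM beats every grid point
  Xn <- withr::with_seed(14, matrix(runif(18 * 2), 18, 2))
  yn <- sin(3 * Xn[, 1]) + withr::with_seed(15, rnorm(18, 0, 0.05))
  gg <- 10^seq(-1, 3); sg <- 10^seq(-1, 3)
  tu2 <- tune_hyperparameters(Xn, yn, "lssvm", gamma_grid = gg,
                              sigma2_grid = sg)
  for (g in gg) for (s in sg) {
    r <- loo_cv(Xn, yn, "lssvm", gamma = g, sigma2 = s)$rmsecv
    expect_gte(r + 1e-12, tu2$rmsecv)
  }
  expect_error(tune_hyperparameters(toy$X, toy$y, "lssvm",
                                    gamma_grid = numeric(0)),
               class = "pectinmap_invalid_argument")
})
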