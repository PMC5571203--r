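test_that("SPA equals exhaustive projection-chain enumeration on a toy", {
  withr::with_seed(77, {
    X <- matrix(rnorm(12 * 6), 12, 6)
    y <- as.numeric(X[, c(2, 5)] %*% c(1.5, -1)) + rnorm(12, 0, 0.1)
  })
  got <- spa_select(X, y, k_min = 1, k_max = 3)
  want <- oracle_spa(X, y, 1, 3)
  expect_identical(got$selected, as.integer(want$set))
  expect_equal(got$diagnostics$rmse, want$rmse, tolerance = 1e-9)
})

test_that("SPA never selects duplicated columns together", {
  withr::with_seed(5, {
    X <- matrix(rnorm(15 * 4), 15, 4)
    X <- cbind(X, X[, 1])            # column 5 duplicates column 1
    y <- rnorm(15)
  })
  res <- spa_select(X, y, k_max = 4)
  expect_false(all(c(1, 5) %in% res$selected))
  ch <- res$diagnostics$winning_chain
  expect_false(all(c(1, 5) %in% ch))
})

test_that("SPA recovers a known support on an orthogonal design", {
  n <- 12
  Q <- qr.Q(qr(withr::with_seed(31, matrix(rnorm(n * 6), n, 6))))
  # orthogonal columns with the support columns carrying the largest norms,
  # so the projection chains reach them and the LOO score singles them out
  X <- Q %*% diag(c(1, 3, 1, 1, 2.5, 1))
  y <- as.numeric(X[, c(2, 5)] %*% c(2, -1))
  res <- spa_select(X, y, k_min = 2, k_max = 2)
  expect_identical(res$selected, c(2L, 5L))
})

test_that("UVE retains informative bands and drops noise bands", {
  n <- 60
  withr::with_seed(1234, {
    t_ <- rnorm(n)
    informative <- outer(t_, rep(1, 10)) +
      matrix(rnorm(n * 10, 0, 0.2), n, 10)
    junk <- matrix(rnorm(n * 90), n, 90)
    y <- t_ + rnorm(n, 0, 0.1)
  })
  X <- cbind(informative, junk)
  res <- uve_select(X, y, n_latent = 5, seed = 99)
  expect_gte(sum(res$selected <= 10), 9)
  expect_lte(sum(res$selected > 10), 5)
  # definitional: no injected noise column survives its own cutoff
  expect_true(all(abs(res$diagnostics$stability_noise) <=
                    res$diagnostics$cutoff))
  # cutoff_factor -> infinity eliminates everything
  expect_error(uve_select(X, y, n_latent = 5, cutoff_factor = 1e12,
                          seed = 99),
               class = "pectinmap_empty_selection")
})

test_that("UVE-SPA selects within the UVE survivors", {
  cfg <- tiny_noisy_config(n_slices = 14, bands = 24, px = 12, seed = 23)
  st <- scene_table(cfg)
  X <- st$table$X; y <- st$table$y$protopectin
  res <- uve_spa_select(X, y, n_latent = 5, seed = 7)
  expect_true(all(res$selected %in% res$diagnostics$uve_survivors))
  # pass-through: if UVE keeps everything, the cascade equals plain SPA
  withr::with_seed(8, {
    Xs <- matrix(rnorm(20 * 5), 20, 5)
    ys <- as.numeric(Xs %*% c(1, 2, -1, 0.5, 0.3)) + rnorm(20, 0, 0.05)
  })
  uve_all <- uve_select(Xs, ys, n_latent = 3, seed = 3)
  if (length(uve_all$selected) == 5) {
    casc <- uve_spa_select(Xs, ys, n_latent = 3, seed = 3)
    plain <- spa_select(Xs, ys, k_max = min(5, nrow(Xs) - 2))
    expect_identical(casc$selected, plain$selected)
  }
})

test_that("CARS retention schedule matches its closed form", {
  r <- cars_ratio_schedule(100, 50)
  a <- 50^(1 / 49); k <- log(50) / 49
  expect_equal(r[1], 1, tolerance = 1e-12)
  expect_equal(r[50], 0.02, tolerance = 1e-12)
  expect_equal(r, a * exp(-k * (1:50)), tolerance = 1e-12)
  expect_true(all(diff(ceiling(r * 100)) <= 0))
})

test_that("CARS finds a planted support and logs a consistent trace", {
  n <- 60; p <- 200
  withr::with_seed(2024, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- rep(0, p); beta[c(10, 50, 90, 130, 170)] <- c(2, -2, 1.5, 2, -1.5)
    y <- as.numeric(X %*% beta) + rnorm(n, 0, 0.2)
  })
  res <- cars_select(X, y, n_runs = 50, seed = 11)
  expect_true(all(c(10, 50, 90, 130, 170) %in% res$selected))
  # schedule trace equals ceiling(r_i * p) with the closed-form constants
  expect_identical(res$diagnostics$schedule_counts,
                   as.integer(ceiling(cars_ratio_schedule(p, 50) * p)))
  # winning subset beats the full spectrum
  full_rmsecv <- tune_hyperparameters(X, y, "plsr",
                                      n_latent_max = 10)$rmsecv
  expect_lte(min(res$diagnostics$rmsecv), full_rmsecv)
  # determinism under seed
  res2 <- cars_select(X, y, n_runs = 50, seed = 11)
  expect_identical(res$selected, res2$selected)
})

test_that("full selection returns all indices and is idempotent", {
  res <- full_selection(512)
  expect_identical(res$selected, 1:512)
  expect_identical(full_selection(1)$selected, 1L)
  expect_identical(full_selection(512)$selected, res$selected)
})

test_that("selection never hurts much on a noiseless scene", {
  cfg <- tiny_noiseless_config(n_slices = 16, bands = 32, px = 14,
                               seed = 41)
  st <- scene_table(cfg)
  X <- st$table$X; y <- st$table$y$protopectin
  full_rmsecv <- tune_hyperparameters(X, y, "plsr")$rmsecv
  sels <- list(spa = spa_select(X, y, k_max = 6),
               uve = uve_select(X, y, n_latent = 5, seed = 2),
               uve_spa = uve_spa_select(X, y, n_latent = 5, seed = 2),
               cars = cars_select(X, y, n_runs = 30, seed = 2))
  for (s in sels) {
    r <- tune_hyperparameters(X[, s$selected, drop = FALSE], y,
                              "plsr")$rmsecv
    expect_lte(r, 1.05 * full_rmsecv + 1e-12)
    expect_true(all(s$selected >= 1 & s$selected <= 32))
  }
})
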