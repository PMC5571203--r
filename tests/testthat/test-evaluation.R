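test_that("metric formulas match hand arithmetic", {
  y <- c(1, 2, 3, 4)
  ycv <- c(1.1, 1.9, 3.2, 3.8)
  rep_ <- compute_metrics(y, y, ycv)
  # hand oracle: sqrt of the mean squared residual
  expect_equal(rep_$rmsecv,
               sqrt((0.1^2 + 0.1^2 + 0.2^2 + 0.2^2) / 4),
               tolerance = 1e-12)
  expect_equal(rep_$rmsec, 0)
  expect_equal(rep_$ab_rmse, rep_$rmsecv, tolerance = 1e-15)
  expect_equal(rep_$rpd, sd(y) / rep_$rmsecv, tolerance = 1e-12)
  # sd(y) = 1, rmsecv = 0.5 gives RPD 2
  y2 <- c(1, 2, 3); stopifnot(abs(sd(y2) - 1) < 1e-12)
  r2 <- compute_metrics(y2, y2, y2 + c(0.5, -0.5, 0.5) / sqrt(1.5) * sqrt(2))
  expect_equal(r2$rpd, sd(y2) / r2$rmsecv, tolerance = 1e-12)
  # perfect CV: infinite RPD sentinel
  expect_identical(compute_metrics(y, y + 0.1, y)$rpd, Inf)
  expect_error(compute_metrics(rep(1, 4), y, ycv),
               class = "pectinmap_degenerate_target")
})

test_that("evaluate_model is deterministic and exact on noiseless data", {
  cfg <- tiny_noiseless_config(n_slices = 12, bands = 32, px = 14)
  st <- scene_table(cfg)
  spec <- model_spec("plsr", selection = "full")
  r1 <- evaluate_model(st$table, spec, "protopectin")
  expect_lt(r1$rmsec, 1e-6)
  expect_lt(r1$ab_rmse, 1e-6)
  r2 <- evaluate_model(st$table, spec, "protopectin")
  expect_identical(r1[c("rmsec", "rmsecv", "rpd")],
                   r2[c("rmsec", "rmsecv", "rpd")])
  expect_error(model_spec("plsr", selection = numeric(0)),
               class = "pectinmap_invalid_argument")
})

test_that("metric invariants hold across an evaluated grid", {
  cfg1 <- tiny_noisy_config(n_slices = 10, bands = 24, px = 12, seed = 61)
  cfg2 <- scene_config("II", n_slices = 10, image_height = 12,
                       image_width = 12, band_count = 20, seed = 62)
  t1 <- scene_table(cfg1)$table
  t2 <- scene_table(cfg2)$table
  grid <- run_model_grid(list(I = t1, II = t2), target = "protopectin",
                         selections = c("full", "spa"),
                         methods = c("plsr", "lssvm"),
                         selector_params = list(spa = list(k_max = 4)),
                         seed = 3)
  cells <- grid$cells
  expect_identical(nrow(cells), 2L * 2L * 2L * 2L)
  ok <- !is.na(cells$rpd)
  expect_true(all(ok))
  for (i in which(ok)) {
    expect_equal(cells$ab_rmse[i], abs(cells$rmsec[i] - cells$rmsecv[i]),
                 tolerance = 1e-15)
    yref <- if (cells$set[i] == "I") t1$y$protopectin else t2$y$protopectin
    expect_equal(cells$rpd[i], sd(yref) / cells$rmsecv[i],
                 tolerance = 1e-12)
    expect_lte(abs(cells$r_cv[i]), 1 + 1e-12)
  }
  # best cell maximizes RPD over all cells
  expect_equal(max(cells$rpd[ok]),
               cells$rpd[cells$model_label == grid$best], tolerance = 1e-12)
  # single-cell grid
  g1 <- run_model_grid(list(I = t1), target = "protopectin",
                       selections = "full", methods = "plsr",
                       preprocess_arms = list(raw = preprocess_spec("none")))
  expect_identical(nrow(g1$cells), 1L)
})

test_that("grid summaries reproduce the worked-example ratios", {
  expect_equal(round(selected_band_percentage(c(8, 4), c(512, 256)), 2),
               1.56)
  expect_equal(round(rmsecv_set_ratio(0.300, 0.646)), 46)
  # marginal means of a constant grid equal the cell value
  cfg <- tiny_noisy_config(n_slices = 8, bands = 12, px = 10, seed = 71)
  tab <- scene_table(cfg)$table
  g <- run_model_grid(list(I = tab), target = "protopectin",
                      selections = "full", methods = "plsr",
                      preprocess_arms = list(raw = preprocess_spec("none")))
  s <- summarize_grid(g)
  for (ax in names(s$marginals))
    expect_equal(s$marginals[[ax]]$rpd, rep(g$cells$rpd[1],
                                            nrow(s$marginals[[ax]])),
                 tolerance = 1e-12)
  expect_equal(unname(s$band_percentage["full"]), 100)
})

test_that("model bundles survive a JSON round trip", {
  cfg <- tiny_noisy_config(n_slices = 8, bands = 16, px = 10, seed = 81)
  st <- scene_table(cfg)
  dir <- withr::local_tempdir()
  for (method in c("plsr", "lssvm")) {
    b <- calibrate_model(st$table, model_spec(method, selection = "full"),
                         "protopectin")
    p <- file.path(dir, paste0(method, ".json"))
    save_model_bundle(b, p)
    b2 <- load_model_bundle(p)
    Xs <- preprocess_matrix(st$table$X, b$preprocess)
    expect_equal(predict(b2$model, Xs[, b2$selection$selected]),
                 predict(b$model, Xs[, b$selection$selected]),
                 tolerance = 1e-12)
    expect_identical(b2$label, b$label)
  }
})
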