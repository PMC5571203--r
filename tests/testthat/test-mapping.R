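fit_small_bundle <- function(seed = 91, noiseless = TRUE) {
  cfg <- if (noiseless) tiny_noiseless_config(n_slices = 10, bands = 24,
                                              px = 16, seed = seed)
         else tiny_noisy_config(n_slices = 10, bands = 24, px = 16,
                                seed = seed)
  st <- scene_table(cfg)
  b <- calibrate_model(st$table, model_spec("plsr", selection = "full"),
                       "protopectin")
  list(st = st, bundle = b, cfg = cfg)
}

test_that("a constant cube maps to a constant prediction", {
  fx <- fit_small_bundle()
  cube1 <- fx$st$scene$cubes[[1]]
  spec0 <- cube1$values[8, 8, ]
  const <- hypercube(array(rep(spec0, each = 16 * 16), c(16, 16, 24)),
                     cube1$wavelengths)
  mask <- fx$st$scene$truth$masks[[1]]
  mp <- predict_map(const, mask, fx$bundle)
  vals <- mp$raw_values[mask]
  expect_lt(max(vals) - min(vals), 1e-10)
  # equals the single-spectrum pipeline prediction
  ab <- -log10(pmax(spec0, 1e-6))
  one <- predict(fx$bundle$model,
                 ab[fx$bundle$selection$selected])
  expect_equal(vals[1], one, tolerance = 1e-10)
})

test_that("map values equal row-wise predictions on extracted spectra", {
  fx <- fit_small_bundle(seed = 92, noiseless = FALSE)
  cube <- fx$st$scene$cubes[[2]]
  mask <- fx$st$scene$truth$masks[[2]]
  mp <- predict_map(cube, mask, fx$bundle)
  px <- extract_pixel_spectra(cube, mask)
  ab <- -log10(pmax(px, 1e-6))
  manual <- predict(fx$bundle$model,
                    ab[, fx$bundle$selection$selected, drop = FALSE])
  # raster order matches extract_pixel_spectra
  got <- t(mp$raw_values)[t(mask)]
  expect_equal(got, manual, tolerance = 1e-12)
  expect_identical(mp$clip_count, sum(manual < 0))
  expect_true(all(mp$values[mask] >= 0))
  # wavelength-axis mismatch is rejected
  bad <- hypercube(cube$values, cube$wavelengths + 5)
  expect_error(predict_map(bad, mask, fx$bundle),
               class = "pectinmap_incompatible_model")
})

test_that("noiseless maps recover the ground-truth fields", {
  fx <- fit_small_bundle(seed = 93)
  for (i in 1:2) {
    cube <- fx$st$scene$cubes[[i]]
    mask <- fx$st$scene$truth$masks[[i]]
    truth <- fx$st$scene$truth$fields[[i]]$protopectin
    mp <- predict_map(cube, mask, fx$bundle)
    mae <- mean(abs(mp$values[mask] - truth[mask]))
    expect_lt(mae, 0.05)
    st_ <- map_stats(mp)
    expect_lt(abs(st_$mean - mean(truth[mask])), 0.05)
  }
})

test_that("map statistics and histogram match a counting oracle", {
  fx <- fit_small_bundle(seed = 94)
  mp <- predict_map(fx$st$scene$cubes[[1]], fx$st$scene$truth$masks[[1]],
                    fx$bundle)
  # direct value checks on a synthetic map object
  mp$values[] <- NA; mp$mask[] <- FALSE
  mp$mask[1, 1:5] <- TRUE
  mp$values[1, 1:5] <- 1:5
  st_ <- map_stats(mp, bin_width = 1)
  expect_equal(st_$mean, 3); expect_equal(st_$min, 1)
  expect_equal(st_$max, 5); expect_equal(st_$sd, sd(1:5))
  expect_equal(sum(st_$histogram$counts), 5)
  # constant map: sd 0, single occupied bin
  mp$values[1, 1:5] <- 2.2
  stc <- map_stats(mp, bin_width = 0.5)
  expect_equal(stc$sd, 0)
  expect_equal(sum(stc$histogram$counts > 0), 1)
  # random map: counts equal a brute-force binning loop
  withr::with_seed(9, mp$values[1, 1:5] <- runif(5, 0, 3))
  bw <- 0.25
  str_ <- map_stats(mp, bin_width = bw)
  v <- mp$values[1, 1:5]
  oracle <- integer(length(str_$histogram$counts))
  for (x in v) {
    b <- min(floor(x / bw) + 1, length(oracle))
    oracle[b] <- oracle[b] + 1L
  }
  expect_identical(str_$histogram$counts, oracle)
})

test_that("pseudo-color rendering is linear, monotone and anchored", {
  fx <- fit_small_bundle(seed = 95)
  mp <- predict_map(fx$st$scene$cubes[[1]], fx$st$scene$truth$masks[[1]],
                    fx$bundle)
  mp$values[] <- NA; mp$mask[] <- FALSE
  mp$mask[1, 1:3] <- TRUE
  mp$values[1, 1:3] <- c(1, 3.5, 6)
  img <- render_pseudocolor(mp, vmin = 1, vmax = 6)
  expect_equal(img[1, 1, ], c(0, 0, 1))   # vmin -> pure blue
  expect_equal(img[1, 3, ], c(1, 0, 0))   # vmax -> pure red
  expect_equal(img[2, 1, ], c(1, 1, 1))   # background -> white
  # affine invariance of the midpoint colour
  mp2 <- mp; mp2$values[1, 1:3] <- 2 * c(1, 3.5, 6) + 10
  img2 <- render_pseudocolor(mp2, vmin = 2 * 1 + 10, vmax = 2 * 6 + 10)
  expect_equal(img2[1, 2, ], img[1, 2, ], tolerance = 1e-12)
  # monotone ramp position
  vals <- seq(0, 1, length.out = 21)
  rgbs <- pectinmap:::pseudocolor_ramp(vals)
  # red channel non-decreasing, blue channel non-increasing along the ramp
  expect_true(all(diff(rgbs[, 1]) >= -1e-12))
  expect_true(all(diff(rgbs[, 3]) <= 1e-12))
  expect_error(render_pseudocolor(mp, vmin = 2, vmax = 2),
               class = "pectinmap_invalid_argument")
})

test_that("write_map emits raster, PNG and stats artifacts", {
  fx <- fit_small_bundle(seed = 96)
  mp <- predict_map(fx$st$scene$cubes[[1]], fx$st$scene$truth$masks[[1]],
                    fx$bundle)
  dir <- withr::local_tempdir()
  paths <- write_map(mp, file.path(dir, "m"))
  expect_true(all(file.exists(paths)))
  back <- read_envi(file.path(dir, "m.bil"))
  vals <- mp$values; vals[is.na(vals)] <- 0
  expect_equal(back$values[, , 1], pectinmap:::as_float32(vals),
               tolerance = 1e-7)
})
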