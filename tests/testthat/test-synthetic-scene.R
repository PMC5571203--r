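test_that("slice mask geometry matches the brute-force ellipse test", {
  # solid ellipse fills ~ pi/4 of the frame
  m <- make_slice_mask(100, 100, 0)
  expect_equal(mean(m), pi / 4, tolerance = 0.01)
  # a pit leaves the centre pixel outside the mask
  m2 <- make_slice_mask(100, 100, 0.2)
  expect_false(m2[50, 50])
  expect_true(sum(m2) < sum(m))
  # exhaustive point-in-ellipse oracle on a rectangular frame
  h <- 64; w <- 96; pit <- 0.15
  oracle <- matrix(FALSE, h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r2 <- ((i - cy) / (h / 2))^2 + ((j - cx) / (w / 2))^2
    oracle[i, j] <- r2 <= 1 && r2 > pit^2
  }
  expect_identical(make_slice_mask(h, w, pit), oracle)
  expect_error(make_slice_mask(0, 10), class = "pectinmap_invalid_argument")
})

test_that("concentration fields hit the requested masked moments", {
  cfg <- scene_config("I", image_height = 40, image_width = 40,
                      band_count = 8, concentration_sd = 0.67)
  mask <- make_slice_mask(40, 40, 0.12)
  f <- sample_concentration_field(cfg, 2.67, mask, seed = 303)
  expect_equal(mean(f[mask]), 2.67, tolerance = 1e-9)
  expect_equal(sd(f[mask]), 0.67, tolerance = 0.02)
  expect_identical(attr(f, "clip_count"), 0L)
  # sd = 0 gives a constant field at the slice mean
  cfg0 <- scene_config("I", image_height = 40, image_width = 40,
                       band_count = 8, concentration_sd = 0)
  f0 <- sample_concentration_field(cfg0, 3.1, mask, seed = 1)
  expect_true(all(f0[mask] == 3.1))
  expect_true(all(f0[!mask] == 0))
  # different seeds differ in pattern but share the masked mean
  f1 <- sample_concentration_field(cfg, 2.67, mask, seed = 304)
  expect_false(isTRUE(all.equal(f, f1, check.attributes = FALSE)))
  expect_equal(mean(f1[mask]), mean(f[mask]), tolerance = 1e-9)
  expect_error(sample_concentration_field(cfg, 2, matrix(FALSE, 40, 40)),
               class = "pectinmap_invalid_argument")
})

test_that("forward spectrum behaves like a Beer-Lambert reflectance model", {
  cfg <- scene_config("I", band_count = 64)
  flat <- forward_spectrum(c(0, 0), cfg)
  expect_equal(flat, rep(cfg$baseline_reflectance, 64))
  wl <- band_wavelengths(380, 1030, 64)
  j <- which.min(abs(wl - 980))          # protopectin band centre
  r1 <- forward_spectrum(c(2, 1), cfg)
  r2 <- forward_spectrum(c(4, 1), cfg)
  expect_lt(r2[j], r1[j])
  expect_error(forward_spectrum(c(-1, 0), cfg),
               class = "pectinmap_invalid_argument")
})

test_that("log reflectance is exactly linear in the concentrations", {
  cfg <- scene_config("I", band_count = 32)
  conc <- cbind(proto = seq(0.5, 5, length.out = 10),
                wsp = seq(2, 0.4, length.out = 10))
  S <- t(apply(conc, 1, function(cc) forward_spectrum(cc, cfg)))
  L <- log(S)
  fit <- lm.fit(cbind(1, conc), L)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # PLSR on the log spectra recovers the concentrations near-exactly
  m <- fit_plsr(L, conc[, 1], 2)
  pred <- predict(m, L)
  expect_lt(sqrt(mean((conc[, 1] - pred)^2)), 1e-8)
})

test_that("generated scenes are deterministic and internally consistent", {
  cfg <- tiny_noiseless_config(n_slices = 2, bands = 24, px = 16)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$cubes[[1]]$values, s2$cubes[[1]]$values)
  expect_identical(s1$truth$references, s2$truth$references)
  expect_identical(dim(s1$cubes[[1]]$values), c(16L, 16L, 24L))
  # pipeline consistency: each masked pixel equals its forward spectrum
  mask <- s1$truth$masks[[1]]
  ij <- which(mask, arr.ind = TRUE)[1, ]
  cc <- c(s1$truth$fields[[1]]$protopectin[ij[1], ij[2]],
          s1$truth$fields[[1]]$water_soluble[ij[1], ij[2]])
  expect_equal(s1$cubes[[1]]$values[ij[1], ij[2], ],
               forward_spectrum(cc, cfg), tolerance = 1e-12)
  # conservation: total = protopectin + water-soluble everywhere
  f <- s1$truth$fields[[2]]
  expect_identical(f$total, f$protopectin + f$water_soluble)
  refs <- s1$truth$references
  expect_equal(refs$total, refs$protopectin + refs$water_soluble)
})

test_that("set I wavelength axis spans 380-1030 nm over 512 bands", {
  cfg <- scene_config("I", n_slices = 1, image_height = 8, image_width = 8)
  expect_identical(cfg$band_count, 512L)
  sc <- generate_scene(cfg)
  wl <- sc$cubes[[1]]$wavelengths
  expect_length(wl, 512)
  expect_equal(wl[1], 380)
  expect_equal(wl[512], 1030)
  expect_true(all(diff(wl) > 0))
  cfg2 <- scene_config("II", n_slices = 1, image_height = 8,
                       image_width = 8)
  expect_identical(cfg2$band_count, 256L)
  expect_equal(cfg2$range_nm, c(874, 1734))
})

test_that("reference_value is the masked mean", {
  mask <- matrix(TRUE, 2, 2)
  expect_identical(reference_value(matrix(3, 2, 2), mask), 3)
  expect_identical(reference_value(matrix(1:4, 2, 2), mask), 2.5)
  # brute-force accumulation oracle
  f <- withr::with_seed(9, matrix(runif(30 * 20), 30, 20))
  m <- withr::with_seed(10, matrix(runif(30 * 20) > 0.4, 30, 20))
  acc <- 0; cnt <- 0
  for (i in 1:30) for (j in 1:20) if (m[i, j]) {
    acc <- acc + f[i, j]; cnt <- cnt + 1
  }
  expect_equal(reference_value(f, m), acc / cnt, tolerance = 1e-12)
  expect_error(reference_value(f, m & FALSE),
               class = "pectinmap_invalid_argument")
})
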