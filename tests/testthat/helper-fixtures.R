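# Shared fixtures: tiny scenes and toy calibration data built in code.

# Small noiseless scene (all pixel-level perturbations off): slice-level
# absorbance spectra are exactly linear in the concentrations.
tiny_noiseless_config <- function(n_slices = 12, bands = 48, px = 20,
                                  seed = 11) {
  scene_config("I", n_slices = n_slices, image_height = px,
               image_width = px, band_count = bands,
               noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
               seed = seed)
}

tiny_noisy_config <- function(n_slices = 12, bands = 48, px = 20,
                              seed = 11) {
  scene_config("I", n_slices = n_slices, image_height = px,
               image_width = px, band_count = bands, seed = seed)
}

scene_table <- function(config) {
  sc <- generate_scene(config)
  list(scene = sc,
       table = build_calibration_table(sc$cubes, sc$truth$masks,
                                       sc$truth$references))
}

# Deterministic random regression problem.
toy_regression <- function(n = 10, p = 5, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    list(X = X, y = y)
  })
}

# A 4x3x2 float32-exact cube for I/O round trips.
toy_cube <- function() {
  v <- array(seq_len(24) / 8, dim = c(4, 3, 2))  # dyadic: float32-exact
  hypercube(v, wavelengths = c(500, 600))
}
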