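# Internal helpers shared across modules.

# Classed error constructor: all package errors carry class
# c("pectinmap_<class>", "pectinmap_error", "error", "condition") so callers
# and tests can dispatch on the failure kind.
pm_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("pectinmap_", class),
                                     "pectinmap_error")))
}

pm_check <- function(cond, msg, class = "invalid_argument") {
  if (!isTRUE(cond)) pm_stop(msg, class)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Root mean square error; NA-free inputs expected.
rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# Derive a deterministic 32-bit sub-seed from a master seed and an index.
# Linear-congruential style mixing keeps everything below 2^31.
derive_seed <- function(master, index) {
  m <- 2147483647
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 69621 +
                12345) %% m)
}

# Quantize doubles to the nearest IEEE single-precision value (the on-disk
# ENVI float32 representation) so round trips are bit-identical.
as_float32 <- function(x) {
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  out <- readBin(rawConnectionValue(con), what = "numeric", n = length(x),
                 size = 4L, endian = "little")
  attributes(out) <- attributes(x)
  out
}
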