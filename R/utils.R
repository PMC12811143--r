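# Internal helpers: error signalling, seeds, angle arithmetic.

sq_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "septaquant_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sq_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) sq_stop(class, msg, ...)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @importFrom withr with_seed
run_seeded <- function(seed, expr) {
  assert_that(is_scalar_num(seed), "invalid_spec", "seed must be a finite scalar")
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream-specific 32-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483647L
}

# Wrap angles (degrees) onto the axial range (-90, 90].
wrap_axial <- function(theta) {
  out <- (theta + 90) %% 180
  out[out == 0] <- 180
  out - 90
}

# Smallest axial angular distance between two angles in degrees (period 180).
axial_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
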