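`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed derived from a user seed and stream indices.
# Kept strictly below 2^31 - 1 so it is always a valid integer seed.
childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 7919 + as.double(i) * 104729 + 17) %% 2147483629
  as.integer(s)
}

# clamp to closed interval
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
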