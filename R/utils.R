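# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Counter-based sub-seed derivation: deterministic in (seed, index, stream),
# independent of how many other sub-seeds were drawn, always in [1, 2^31 - 2].
derive_seed <- function(seed, index, stream = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(seed) %% m) * 48271 %% m
  x <- (x + as.double(index) * 16807) %% m
  x <- (x * 69621 + as.double(stream) * 30269) %% m
  as.integer(x %% (m - 1)) + 1L
}

stop_hotspotr <- function(msg, class) {
  abort(msg, class = c(class, "hotspotr_error"))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_hotspotr(sprintf("`%s` must be a single finite number.", name),
                  "hotspotr_validation_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
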