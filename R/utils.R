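# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(index)) %% 2147483629L)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. A NULL seed evaluates in the current state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "markscape_validation_error")
}

stop_state <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "markscape_state_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_validation("`%s` must be in [%g, %g], got %g", name, lower, upper, x)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_validation("`%s` must be an integer, got %g", name, x)
  invisible(as.integer(x))
}
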