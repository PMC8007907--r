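## Internal validation helpers shared across modules.

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

## Deterministic seeding that restores the caller's RNG state on exit.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  seed <- assert_count(seed, "seed", min = -.Machine$integer.max)
  withr::local_seed(seed, .local_envir = env)
  invisible(seed)
}

## Square numeric matrix check used by similarity consumers.
assert_square <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != ncol(x)) {
    abort(sprintf("`%s` must be a square numeric matrix.", name))
  }
  invisible(x)
}
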