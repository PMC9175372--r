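## Internal validation helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

assert_prob <- function(x, name, open = TRUE) {
  assert_scalar_num(x, name)
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok)
    stopf("'%s' must lie in %s, got %g", name,
          if (open) "(0, 1)" else "[0, 1]", x)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_num(x, name)
  if (x != round(x) || x < min)
    stopf("'%s' must be an integer >= %d, got %g", name, min, x)
  invisible(as.integer(x))
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG
## stream; with seed = NULL the global stream is used as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
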