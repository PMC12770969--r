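## Internal helpers shared across the package.

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards.  All exported functions that take a
## `seed` argument funnel their randomness through this, so library calls
## never clobber the user's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a reproducible child seed from a base seed and a stream index,
## staying inside the 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index * 7919) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_param("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_param("'%s' must be a probability in [0, 1]", name)
  as.numeric(x)
}
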