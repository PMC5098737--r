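# internal helpers

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# `seed` NULL means: use the current stream (still reproducible if the caller
# seeded it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample SD that returns 0 (not NA) for n = 1
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

stop_renalmr <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_renalmr(...)
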