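# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.  All exported stochastic functions route
# their randomness through this so that a single seed argument fully
# determines their output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a session seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, k) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 69621 + as.numeric(k) * 7919 + 1) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Half-open interval membership [a, b) on a sample grid.
samples_in <- function(t, a, b) which(t >= a & t < b)
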