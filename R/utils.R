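# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb user-level randomness.
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Largest-remainder apportionment of n units by positive weights.
# Ties in fractional remainder are broken by position (earlier wins),
# which keeps the result deterministic.
largest_remainder <- function(n, weights) {
  stopifnot(n >= 0, all(weights > 0))
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    frac <- quota - base
    give <- order(-frac, seq_along(frac))[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}
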