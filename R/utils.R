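# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-purpose sub-seed; keeps the result inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset)
}

# Total overlap (bp) of interval [start, end] with a set of intervals
# given as a 2-column matrix (start, end), all 1-based inclusive.
interval_overlap <- function(start, end, ivs) {
  if (is.null(ivs) || nrow(ivs) == 0) {
    return(0)
  }
  lo <- pmax(start, ivs[, 1])
  hi <- pmin(end, ivs[, 2])
  sum(pmax(0, hi - lo + 1))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
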