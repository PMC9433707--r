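# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and an index, kept inside the 32-bit
# integer range so set.seed() accepts it.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 8191) %% 2147483629)
}

# Round half away from zero: the sample-index rounding rule used everywhere an
# onset time or a duration is converted to samples.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

rms <- function(x) sqrt(mean(x^2))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
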