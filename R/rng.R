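# Seed plumbing for the synthetic-data generator.
#
# Every stochastic draw in the simulator runs inside `with_seed()` under a
# stream id derived from the master seed with `mix_seed()`, so duplicate
# injections share their extract-level draws while everything stays fully
# reproducible from a single integer, and user-level RNG state is untouched.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically fold integer components into one 31-bit stream id.
mix_seed <- function(...) {
  v <- as.numeric(c(...))
  s <- 0
  for (x in v) s <- (s * 69069 + x + 1) %% 2147483629
  as.integer(s)
}
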