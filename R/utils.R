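# Deterministic seed substreams. A master seed spawns per-unit seeds via a
# Lehmer-style mixing step, kept strictly inside 32-bit integer range so the
# result is always a valid set.seed() input.
.td_derive_seed <- function(master, index) {
  m <- 2147483647
  x <- (as.double(master) %% m) + 1
  for (i in seq_len(2)) {
    x <- (x * 48271 + as.double(index) * 16807 + 11) %% m
  }
  as.integer(x)
}

# Run code under a seed without disturbing the caller's RNG state.
# seed = NULL leaves the current stream untouched.
.td_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
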