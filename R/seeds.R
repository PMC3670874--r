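# Deterministic seed plumbing. One master seed fans out to the simulator,
# the CV splits and the per-(fold, cell) ELM weight draws so that a whole
# run is reproducible while sub-streams stay decorrelated.

# Mixes a master seed with integer indices into a new seed in [1, 2^31 - 2].
# Multiplications stay below 2^53 so doubles carry them exactly.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s + 1)
}

# Runs `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  expr
}
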