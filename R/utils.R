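# internal helpers

# Evaluate `code` under a local RNG stream: seeds explicitly, then restores
# whatever global RNG state existed before. Keeps every stochastic routine
# deterministic given its seed argument without touching callers' streams.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed (kept within 32-bit integer range; arithmetic in
# doubles so large parent seeds cannot overflow)
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% 2147483647)
}
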