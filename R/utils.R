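## Internal helpers.

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG
## state afterwards.  All randomized package internals are seeded through
## this, so results are reproducible from config seeds alone and never
## perturb (or depend on) the global RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

## Deterministic sub-seed derivation (kept below 2^31).
subSeed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}

## Inverse-CDF categorical draw from shared uniforms (common random
## numbers across two stimulus distributions use the same u).
categoricalFromUniform <- function(u, probs) {
  findInterval(u, cumsum(probs / sum(probs)), left.open = TRUE) + 1L
}
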