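## Evaluate an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards. All stochastic generators
## in the package route through this, which is what makes every artifact a
## pure function of (inputs, seed).
withRNG <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("'seed' must be coercible to an integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

## Derive a stream of sub-seeds from a master seed (kept below 2^31).
deriveSeeds <- function(seed, n) {
  withRNG(seed, sample.int(.Machine$integer.max - 1L, n))
}
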