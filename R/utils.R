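# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All package randomness flows through this helper so that every
# stochastic operation is reproducible from one integer seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629)
}

# Two-sided normal tail probability computed on the log scale so that
# extreme Z scores do not underflow to zero prematurely.
p_from_z <- function(z) {
  exp(stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2))
}

# -log10 of a two-sided normal tail probability, safe for very large |z|.
neglog10_p_from_z <- function(z) {
  -(stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}

# Floor p-values away from zero before taking logs (documented behaviour of
# the r2_equiv and RSS statistics).
floor_p <- function(p, floor = 1e-320) {
  pmax(p, floor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
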