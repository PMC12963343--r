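# Shared helpers: seeded evaluation, seed derivation, rounding.

# Evaluate `code` under a temporary RNG state; the caller's stream is
# untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministically mix integers into one seed < 2^31 - 1. Products stay
# below 2^53 so double arithmetic is exact.
derive_seed <- function(...) {
  m <- 2147483629
  s <- 0
  for (a in c(...)) s <- (s * 48271 + (as.numeric(a) %% m) + 11) %% m
  as.integer(s) + 1L
}

# Round half away from zero (the convention used for printed percentages).
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
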