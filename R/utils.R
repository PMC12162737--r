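# internal helpers shared across modules

# Deterministic sub-seed derivation; stays below 2^31 - 1.
mix_seed <- function(seed, a = 0L, b = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  s <- (s * 1000003 + as.double(a) * 10007 + as.double(b) * 101) %% 2147483647
  as.integer(s)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
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

# Standard normal truncated at +/- 3 sd (keeps per-subject jitter bounded).
rnorm_trunc3 <- function(n) {
  z <- rnorm(n)
  while (any(bad <- abs(z) > 3)) z[bad] <- rnorm(sum(bad))
  z
}

# Half-up rounding (round() ties-to-even would turn 62.5% into 62%).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

stopf <- function(...) abort(sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
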