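# Internal plumbing: deterministic seed derivation and scoped RNG use.
#
# Every source of randomness in the package flows from a single master seed
# through `derive_seed()`, a counter-based multiplicative-congruential mix.
# Child seeds are reproducible in isolation (any cycle/fold/tree can be
# re-derived without replaying the whole run) and stay below 2^31 so they
# are valid arguments to `set.seed()`.

# Modulus and multiplier of the classic Lehmer generator; all arithmetic is
# exact in doubles (2147483629 * 48271 < 2^53).
.seed_mod <- 2147483629

derive_seed <- function(seed, ...) {
  counters <- c(...)
  s <- as.numeric(seed) %% .seed_mod
  for (k in c(0, counters)) {
    s <- (s * 48271 + k + 1) %% .seed_mod
  }
  # keep away from 0 which some generators treat specially
  s + 1
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(derive_seed(seed) %% 2147483647))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}
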