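# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. With seed = NULL the expression simply
# consumes the global RNG stream, so unseeded calls behave like ordinary
# stochastic R functions.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# Deterministically derive `n` child seeds from a master seed, so that every
# source in an ensemble (or every cell in a sweep) gets an independent,
# collision-free RNG stream. Seeds stay within the 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Round half-up: values with fractional part exactly 0.5 go to the next
# larger integer (unlike base::round, which rounds half to even).
round_half_up <- function(x) {
  floor(x + 0.5)
}

stop_input <- function(...) {
  stop(..., call. = FALSE)
}
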