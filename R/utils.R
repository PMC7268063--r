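# Internal RNG helpers.
#
# All stochastic steps draw from locally seeded streams so that results are
# reproducible and independent of the caller's RNG state. Per-resample
# streams are derived from (seed, fold, b): growing NB appends resamples
# without changing earlier ones, and a single-config run reproduces the
# matching cell of a grid search.

.MOD31 <- 2147483647 # 2^31 - 1; R seeds must stay below 2^31

# Deterministic stream seed from up to three small non-negative integers.
# Double arithmetic is exact here (all intermediates < 2^53).
stream_seed <- function(seed, fold = 0L, b = 0L) {
  s <- (as.double(seed) %% .MOD31)
  s <- (s * 69069 + as.double(fold) * 1000003 + 1) %% .MOD31
  s <- (s * 69069 + as.double(b) * 10007 + 1) %% .MOD31
  as.integer(s)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
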