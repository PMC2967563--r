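# Internal helpers: logging, seed streams, RNG scoping.

nca_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

nca_warn <- function(stage, fmt, ...) {
  warning(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

# Stage-indexed substream derivation from a single top-level seed, so that
# inserting a pipeline stage does not perturb the draws of later stages.
# Result is always in [1, 2^31 - 2] (valid set.seed() input).
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + h * 9973 + as.numeric(index) * 877) %% m
  as.integer(x %% (m - 1) + 1)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
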