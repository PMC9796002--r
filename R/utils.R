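# internal numeric helpers shared across modules

# log(1 + exp(x)) without overflow for large |x|
softplus <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# inverse logit kept strictly inside (0, 1): the linear predictor is clipped
# in log space at +/-36 (|delta| = 36 leaves p one ulp away from 0/1), the
# probability itself is never truncated
inv_logit <- function(x) stats::plogis(pmin(pmax(x, -36), 36))

SECONDS_PER_BIN <- 900L

# evaluate `code` under a temporary RNG seed, restoring global RNG state so
# seeded simulator calls leave no hidden side effects
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
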