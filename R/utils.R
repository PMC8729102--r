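#' @importFrom stats rnorm runif rbinom plogis qnorm pnorm dnorm median sd
#'   complete.cases setNames
#' @importFrom utils combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-patient substream seed: prefixes are invariant to the
# cohort size because each patient draws from her own counter-keyed stream.
patient_seed <- function(seed, stage, i) {
  ((as.integer(seed) %% 1000003L) * 1009L + as.integer(stage) * 101L +
     as.integer(i)) %% 2147483647L
}

# One-decimal percentage; round() is round-half-even in R.
percent1 <- function(num, den) {
  stopifnot(den > 0, num <= den)
  round(100 * num / den, 1)
}

stop_domain <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
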