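# Numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(x) {
  x <- as_mat(x)
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# An isolated RNG stream: consuming it never disturbs (and is never disturbed
# by) the global .Random.seed, so seeded operations compose deterministically.
local_rng <- function(seed) {
  rng <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  rng$state <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  rng
}

with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

rng_sample <- function(rng, n, k) with_rng(rng, sample.int(n, k))

rng_runif <- function(rng, n, min = 0, max = 1) {
  with_rng(rng, stats::runif(n, min, max))
}

rng_rnorm <- function(rng, n, mean = 0, sd = 1) {
  with_rng(rng, stats::rnorm(n, mean, sd))
}

# Deterministic derived seed for a named substream, kept within 32-bit range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}
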