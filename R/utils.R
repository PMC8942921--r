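# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded operations compose without side effects.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Fan a single user-facing seed out to per-stage seeds (gametes, W reads,
# M reads, null band, ...) so stages draw from disjoint, reproducible streams.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  ((abs(as.integer(seed)) %% 1000003L) * 2039 + as.integer(stage) * 7919) %%
    2147483646L + 1L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 &&
    abs(x - round(x)) < 1e-8
}
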