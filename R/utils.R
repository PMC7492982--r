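# Internal numeric and RNG helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# user-level random streams.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: all randomness in a run flows from one
# master seed through named/indexed substreams. Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807 + 12345) %%
               2147483647)
}

# Population (divide-by-n) standard deviation; 0 for fewer than 1 value.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(0)
  m <- mean(x)
  sqrt(sum((x - m)^2) / n)
}

# Rank-based (Mann-Whitney) AUC of scores for a logical positive-class
# indicator; ties handled by midranks. NA when either class is absent.
auc_score <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
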