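# Internal numerical helpers.

# log(sum(exp(x))) with the usual max shift; x a numeric vector.
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp over the columns of a matrix (small, fixed width).
row_lse <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx + log(rowSums(exp(m - mx)))
}

# Deterministic per-stage seed derivation from one master seed.
# Stage indices are small integers fixed per pipeline stage; the rule is
# stable across versions so any artifact can be regenerated from its config.
split_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(stage) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)
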