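# Internal helpers shared across modules.

# Derive a reproducible 32-bit stage seed from a master seed and a stage index.
# Kept strictly below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stage)) %% 2147483629L)
}

# Normalize chromosome labels: strip a leading "chr"/"Chr" prefix.
normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Upper-tail chi-square(1) p-value, vectorized, safe for statistic = 0.
chisq1_p <- function(stat) stats::pchisq(stat, df = 1, lower.tail = FALSE)
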