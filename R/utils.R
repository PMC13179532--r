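# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% (.Machine$integer.max - 1L)) + 1L
}

# Row-wise log-sum-exp of a matrix of log-terms.
row_logsumexp <- function(lw) {
  m <- apply(lw, 1L, max)
  m + log(rowSums(exp(lw - m)))
}

stop_input <- function(...) stop(..., call. = FALSE)
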