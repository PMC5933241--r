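# Independent oracles, deliberately naive, used to cross-check the package's
# vectorised implementations.

# overlap-allowed substring count by direct position-by-position comparison
naive_word_count <- function(block, word) {
  n <- nchar(block)
  k <- nchar(word)
  sum(vapply(seq_len(n - k + 1), function(s) {
    substr(block, s, s + k - 1) == word
  }, logical(1)))
}

# pooled proportion of 1 digits in a dataset
digit_matrix_prop <- function(d) {
  mean(as.integer(charToRaw(paste(d$block, collapse = ""))) - 48L)
}

random_block <- function(n) {
  paste(sample(c("0", "1"), n, replace = TRUE), collapse = "")
}

# frozen exact values, computed by full enumeration of all 2^20 blocks and
# independently confirmed by a brute-force substring scan
EXACT_RATE_0000_N20 <- 0.47801876068115234
EXACT_RATE_0001_N20 <- 0.74624729156494141
EXACT_MASS0_0000_N20 <- 0.52198123931884766
EXACT_MASS0_0001_N20 <- 0.25375270843505859
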