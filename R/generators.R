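#' Seeded binary-block generators
#'
#' Three generating processes for datasets of fixed-length binary blocks,
#' each block independent of the others (mirroring the distractor-task breaks
#' between experimental blocks):
#'
#' * `generate_bernoulli()`: digits i.i.d. with `P(0) = base_rate`;
#'   `base_rate = 0.5` is the theoretically unbiased (TU) source.
#' * `generate_markov()`: the first digit of each block is unbiased; each
#'   later digit equals the previous one with probability `1 - switch_rate`
#'   and flips with probability `switch_rate`. `switch_rate = 0.5` is again
#'   unbiased.
#' * `generate_boost()`: the one-parameter model of human sequence
#'   production. The first `k - 1` digits of a block are unbiased warm-up;
#'   every later digit looks at the previous `k - 1` digits (the sliding
#'   window of experience minus the digit about to be produced). If that
#'   context equals the first `k - 1` symbols of the boosted word `w`, the
#'   digit completes `w` with probability `beta`; if it equals the first
#'   `k - 1` symbols of the complement of `w`, it completes the complement
#'   with probability `beta`; otherwise the digit is a fair bit. With the
#'   default pair `0001/1110` and `beta > 0.5` this boosts the probability
#'   of breaking a run of three identical outcomes — the gambler's-fallacy
#'   signature — while `beta = 0.5` reduces every case to the unbiased
#'   source.
#'
#' All three accept a `seed` and then return bit-identical datasets across
#' runs; digit draws consume the RNG stream position by position across all
#' blocks at once.
#'
#' @param n_blocks Number of blocks to generate.
#' @param n Block length (default 20).
#' @param base_rate Probability of emitting a 0 at each position.
#' @param switch_rate Probability that a digit differs from its predecessor.
#' @param pair Boosted complementary pair (any form accepted by
#'   [pair_count_distribution()]); its length sets the window length `k`.
#' @param beta Boost probability in `[0, 1]`.
#' @param warmup `"embedded"` (default): the `k - 1` warm-up digits are the
#'   first `k - 1` digits of each block, so blocks are exactly `n` digits.
#'   `"prepended"`: warm-up digits are generated before the block and
#'   discarded, so all `n` retained digits are context-conditioned (for
#'   sensitivity analysis).
#' @param seed Optional integer seed.
#' @param participant,condition,phase Labels for the resulting dataset.
#' @return A sequence dataset tibble (see [sequence_dataset()]).
#' @examples
#' generate_boost(5, pair = "0001", beta = 0.9, seed = 1)
#' @name generators
NULL

#' @rdname generators
#' @export
generate_bernoulli <- function(n_blocks, n = 20, base_rate = 0.5, seed = NULL,
                               participant = "sim", condition = "synthetic",
                               phase = "generate") {
  check_prob(base_rate, "base_rate")
  check_blocks_n(n_blocks, n)
  if (!is.null(seed)) withr::local_seed(seed)
  dm <- matrix(as.integer(stats::runif(n_blocks * n) >= base_rate),
               nrow = n_blocks, ncol = n)
  sequence_dataset(digits_to_blocks(dm), participant = participant,
                   condition = condition, phase = phase)
}

#' @rdname generators
#' @export
generate_markov <- function(n_blocks, n = 20, switch_rate = 0.5, seed = NULL,
                            participant = "sim", condition = "synthetic",
                            phase = "generate") {
  check_prob(switch_rate, "switch_rate")
  check_blocks_n(n_blocks, n)
  if (!is.null(seed)) withr::local_seed(seed)
  dm <- matrix(0L, nrow = n_blocks, ncol = n)
  dm[, 1] <- as.integer(stats::runif(n_blocks) < 0.5)
  for (i in seq_len(n)[-1]) {
    flip <- stats::runif(n_blocks) < switch_rate
    dm[, i] <- ifelse(flip, 1L - dm[, i - 1], dm[, i - 1])
  }
  sequence_dataset(digits_to_blocks(dm), participant = participant,
                   condition = condition, phase = phase)
}

#' @rdname generators
#' @export
generate_boost <- function(n_blocks, n = 20, pair = "0001", beta = 0.5,
                           warmup = c("embedded", "prepended"), seed = NULL,
                           participant = "sim", condition = "synthetic",
                           phase = "generate") {
  check_prob(beta, "beta")
  check_blocks_n(n_blocks, n)
  warmup <- match.arg(warmup)
  pair <- resolve_pair(pair)
  k <- nchar(pair[1])
  if (k < 2) stop("boosting needs a word of length k >= 2.", call. = FALSE)
  if (k > n) {
    stop("window length k = ", k, " exceeds block length n = ", n, ".",
         call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  dm <- boost_digits(n_blocks, n, pair, beta, warmup)
  sequence_dataset(digits_to_blocks(dm), participant = participant,
                   condition = condition, phase = phase)
}

# digit matrix of the boost process; RNG state is the caller's
boost_digits <- function(n_blocks, n, pair, beta, warmup = "embedded") {
  k <- nchar(pair[1])
  total <- if (warmup == "prepended") n + k - 1 else n
  w <- as.integer(strsplit(pair[1], "")[[1]])
  w_prefix <- sum(w[-k] * 2^((k - 2):0))
  wbar_prefix <- sum((1L - w[-k]) * 2^((k - 2):0))
  w_last <- w[k]
  # probability the next digit is 1, given each matching context
  p1_w <- if (w_last == 1) beta else 1 - beta
  p1_wbar <- 1 - p1_w  # the complement word ends in 1 - w_last
  pw <- 2^((k - 2):0)
  dm <- matrix(0L, nrow = n_blocks, ncol = total)
  dm[, seq_len(k - 1)] <- as.integer(stats::runif(n_blocks * (k - 1)) < 0.5)
  for (i in k:total) {
    ctx <- as.integer(dm[, (i - k + 1):(i - 1), drop = FALSE] %*% pw)
    p1 <- rep(0.5, n_blocks)
    p1[ctx == w_prefix] <- p1_w
    p1[ctx == wbar_prefix] <- p1_wbar
    dm[, i] <- as.integer(stats::runif(n_blocks) < p1)
  }
  if (warmup == "prepended") dm[, k:total, drop = FALSE] else dm
}

check_blocks_n <- function(n_blocks, n) {
  if (length(n_blocks) != 1 || n_blocks < 1 || n_blocks != round(n_blocks)) {
    stop("`n_blocks` must be a single positive integer.", call. = FALSE)
  }
  if (length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer.", call. = FALSE)
  }
  invisible(NULL)
}
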