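#' Pattern-matching automaton for a binary word
#'
#' Builds the deterministic automaton whose states are the matched-prefix
#' lengths `0..k` of `word`, with transitions derived from the
#' longest-proper-prefix-that-is-a-suffix (failure) function, as in
#' Knuth-Morris-Pratt matching. Reading a block symbol by symbol, the
#' automaton enters state `k` exactly once per sliding-window occurrence of
#' the word (overlaps included), which makes the exact occurrence statistics
#' of an unbiased source a small transition-probability propagation instead
#' of a `2^n` enumeration.
#'
#' @param word A binary word.
#' @return An object of class `word_automaton`: a list with `word`, `k`, and
#'   `transitions`, a `(k+1) x 2` integer matrix whose `[j+1, c+1]` entry is
#'   the state reached from state `j` on symbol `c`.
#' @examples
#' build_word_automaton("00")$transitions
#' @export
build_word_automaton <- function(word) {
  check_word(word)
  pat <- as.integer(strsplit(word, "")[[1]])
  k <- length(pat)
  # failure function: border[j] = longest proper prefix of pat[1:j] that is
  # also a suffix
  border <- integer(k)
  for (j in seq_len(k)[-1]) {
    b <- border[j - 1]
    while (b > 0 && pat[b + 1] != pat[j]) b <- border[b]
    border[j] <- if (pat[b + 1] == pat[j]) b + 1L else 0L
  }
  delta <- matrix(0L, nrow = k + 1, ncol = 2,
                  dimnames = list(paste0("s", 0:k), c("0", "1")))
  for (c in 0:1) delta[1, c + 1] <- if (pat[1] == c) 1L else 0L
  if (k >= 2) {
    for (j in 1:(k - 1)) {
      for (c in 0:1) {
        delta[j + 1, c + 1] <-
          if (pat[j + 1] == c) j + 1L else delta[border[j] + 1, c + 1]
      }
    }
  }
  # from a full match, continue as from its longest border
  for (c in 0:1) delta[k + 1, c + 1] <- delta[border[k] + 1, c + 1]
  structure(list(word = word, k = k, transitions = delta),
            class = "word_automaton")
}

#' Exact count distribution of a word in an unbiased block
#'
#' Probability distribution of the number of sliding-window occurrences of
#' `word` in a length-`n` block whose digits are i.i.d. fair bits. Two
#' independent computations are available: `"automaton"` propagates the joint
#' (automaton state, match count) distribution for `n` steps and works for
#' any `n`; `"enumeration"` scans all `2^n` blocks and is limited to
#' `n <= 24`. They agree to machine precision and each is used to test the
#' other.
#'
#' @param word A binary word of length `k`.
#' @param n Block length, `n >= k`.
#' @param method `"automaton"` (default) or `"enumeration"`.
#' @return A tibble with columns `count` (`0 .. n-k+1`) and `probability`,
#'   summing to 1. The expectation is `(n-k+1)/2^k` for every word.
#' @examples
#' exact_count_distribution("0000", n = 4)
#' @export
exact_count_distribution <- function(word, n,
                                     method = c("automaton", "enumeration")) {
  check_word(word)
  method <- match.arg(method)
  k <- nchar(word)
  if (k > n) {
    stop("word length k = ", k, " exceeds block length n = ", n, ".",
         call. = FALSE)
  }
  W <- n - k + 1
  probs <- switch(method,
    automaton = {
      delta <- build_word_automaton(word)$transitions
      # P[state + 1, count + 1]
      P <- matrix(0, nrow = k + 1, ncol = W + 1)
      P[1, 1] <- 1
      for (step in seq_len(n)) {
        Q <- matrix(0, nrow = k + 1, ncol = W + 1)
        for (j in 0:k) {
          row <- P[j + 1, ]
          if (all(row == 0)) next
          for (c in 0:1) {
            ns <- delta[j + 1, c + 1]
            if (ns == k) {
              Q[ns + 1, 2:(W + 1)] <- Q[ns + 1, 2:(W + 1)] + 0.5 * row[1:W]
            } else {
              Q[ns + 1, ] <- Q[ns + 1, ] + 0.5 * row
            }
          }
        }
        P <- Q
      }
      colSums(P)
    },
    enumeration = {
      counts <- enumerate_counts(word, n)
      tabulate(counts + 1L, nbins = W + 1) / 2^n
    }
  )
  tibble::tibble(count = 0:W, probability = probs)
}

#' Exact occurrence rate of a word in an unbiased block
#'
#' Probability that `word` occurs at least once among the `n - k + 1` sliding
#' windows of an unbiased length-`n` block: the complement of the
#' nonoccurrence probability that drives the sliding-window account of
#' randomness perception. For runs such as `0000` at `n = 20` this is only
#' about 0.478 even though the expected frequency (1.0625) equals every other
#' word's.
#'
#' @inheritParams exact_count_distribution
#' @return A single probability.
#' @examples
#' exact_occurrence_rate("0000", n = 20)
#' @export
exact_occurrence_rate <- function(word, n,
                                  method = c("automaton", "enumeration")) {
  d <- exact_count_distribution(word, n, method = match.arg(method))
  1 - d$probability[1]
}

# per-block occurrence counts of `word` across all 2^n blocks (bit-parallel
# scan; each block encoded as an integer, most significant bit first)
enumerate_counts <- function(word, n) {
  k <- nchar(word)
  if (n > 24) {
    stop("full enumeration is limited to n <= 24 (2^n blocks); ",
         "use method = \"automaton\".", call. = FALSE)
  }
  v <- strtoi(word, base = 2L)
  x <- 0:(2^n - 1)
  mask <- bitwShiftL(1L, k) - 1L
  counts <- integer(length(x))
  for (s in 0:(n - k)) {
    counts <- counts + (bitwAnd(bitwShiftR(x, s), mask) == v)
  }
  counts
}

#' Exact reference table for the theoretically unbiased source
#'
#' Per-word exact statistics of an unbiased (fair Bernoulli) source at block
#' length `n` and window length `k`: the occurrence rate, the expected
#' frequency per block (identical across words at `(n-k+1)/2^k`), and the
#' probability of zero occurrences. This is the "theoretically unbiased"
#' (TU) reference against which generated data are compared.
#'
#' @param n Block length (default 20).
#' @param k Window length (default 4).
#' @param method Passed to [exact_count_distribution()].
#' @return A tibble of class `tu_reference` with columns `word`, `rate`,
#'   `expected_frequency`, `mass_at_0`.
#' @examples
#' tu_reference(n = 8, k = 3)
#' @export
tu_reference <- function(n = 20, k = 4,
                         method = c("automaton", "enumeration")) {
  method <- match.arg(method)
  k <- check_k(k)
  words <- all_words(k)
  rows <- purrr::map(words, function(w) {
    d <- exact_count_distribution(w, n, method = method)
    tibble::tibble(
      word = w,
      rate = 1 - d$probability[1],
      expected_frequency = sum(d$count * d$probability),
      mass_at_0 = d$probability[1]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tu_reference", class(out))
  attr(out, "n") <- n
  attr(out, "k") <- k
  out
}

#' Monte-Carlo confidence bounds for a finite unbiased dataset
#'
#' Repeatedly simulates datasets of `n_blocks` unbiased blocks and returns,
#' per word, the percentile interval of the chosen sliding-window statistic
#' across replicates. This quantifies how far a finite sample of the
#' unbiased source can stray from the exact reference — the dashed
#' confidence bands drawn around the TU curves.
#'
#' @param n_blocks Blocks per replicate dataset (360 matches a 12-participant
#'   session of 30 blocks).
#' @param n Block length.
#' @param k Window length.
#' @param reps Number of replicate datasets (>= 2; 1000 by default).
#' @param seed Optional integer seed for reproducibility.
#' @param metric `"occurrence_rate"` (Analysis 2) or `"average_frequency"`
#'   (Analysis 1).
#' @param level Confidence level for the percentile interval (default 0.95).
#' @return A tibble with columns `word`, `lower`, `median`, `upper`.
#' @examples
#' tu_replicate_ci(n_blocks = 60, reps = 50, seed = 1)
#' @export
tu_replicate_ci <- function(n_blocks, n = 20, k = 4, reps = 1000, seed = NULL,
                            metric = c("occurrence_rate", "average_frequency"),
                            level = 0.95) {
  metric <- match.arg(metric)
  k <- check_k(k)
  if (reps < 2) stop("`reps` must be at least 2.", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  B <- n_blocks * reps
  dm <- matrix(as.integer(stats::runif(B * n) < 0.5), nrow = B, ncol = n)
  wv <- window_values(dm, k)
  rep_id <- rep(seq_len(reps), each = n_blocks)
  alpha <- (1 - level) / 2
  words <- all_words(k)
  rows <- purrr::map(seq_along(words), function(i) {
    per_block <- rowSums(wv == (i - 1L))
    stat <- if (metric == "occurrence_rate") {
      rowsum(as.numeric(per_block > 0), rep_id)[, 1] / n_blocks
    } else {
      rowsum(per_block, rep_id)[, 1] / n_blocks
    }
    q <- stats::quantile(stat, c(alpha, 0.5, 1 - alpha), names = FALSE)
    tibble::tibble(word = words[i], lower = q[1], median = q[2], upper = q[3])
  })
  dplyr::bind_rows(rows)
}
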