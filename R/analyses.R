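#' Average word frequency per block (Analysis 1)
#'
#' Mean number of sliding-window occurrences of each length-`k` word per
#' block, averaged over all blocks of the dataset. Under an unbiased source
#' every word has the same expectation, `(n-k+1)/2^k` (1.0625 for the default
#' 20-bit block and 4-bit window), so departures in this statistic are the
#' classical evidence for "biased" sequence production.
#'
#' @param data A sequence dataset (see [sequence_dataset()]).
#' @param k Window length.
#' @return A tibble with columns `word` and `frequency`; frequencies sum to
#'   `n - k + 1` across words.
#' @examples
#' d <- generate_bernoulli(100, seed = 1)
#' average_frequency(d)
#' @export
average_frequency <- function(data, k = 4) {
  wv <- dataset_window_values(data, k)
  tibble::tibble(
    word = all_words(k),
    frequency = tabulate(as.vector(wv) + 1L, nbins = 2^k) / nrow(wv)
  )
}

#' Word occurrence rate (Analysis 2)
#'
#' Proportion of blocks containing at least one sliding-window occurrence of
#' each word — the sample analogue of [exact_occurrence_rate()], and the
#' statistic on which human-generated sequences track an unbiased source most
#' closely. Blocks are pooled across participants.
#'
#' @inheritParams average_frequency
#' @return A tibble with columns `word` and `rate` (each in `[0, 1]`).
#' @examples
#' occurrence_rate(generate_bernoulli(360, seed = 1))
#' @export
occurrence_rate <- function(data, k = 4) {
  wv <- dataset_window_values(data, k)
  words <- all_words(k)
  rate <- vapply(seq_along(words), function(i) {
    mean(rowSums(wv == (i - 1L)) > 0)
  }, numeric(1))
  tibble::tibble(word = words, rate = rate)
}

#' Pooled count distribution for a complementary pair (Analysis 3)
#'
#' Per-block occurrence counts of a word and of its bitwise complement,
#' pooled into one histogram (each block contributes two counts, one per pair
#' member). Pooling uses the 0/1 symmetry of the source; the pair histograms
#' for runs (`0000/1111`), near-runs (`0001/1110`) and alternations
#' (`0101/1010`) differ markedly even for an unbiased source.
#'
#' @inheritParams average_frequency
#' @param pair A complementary pair: one word, both words, or a
#'   `"word/complement"` label.
#' @return A tibble with columns `count` (0 to `n - k + 1`) and `proportion`,
#'   summing to 1; its mean equals the average of the two words' Analysis-1
#'   frequencies.
#' @examples
#' pair_count_distribution(generate_bernoulli(100, seed = 1), "0000")
#' @export
pair_count_distribution <- function(data, pair, k = 4) {
  counts <- pooled_pair_counts(data, pair, k)
  W <- nchar(validate_dataset(data)$block[1]) - check_k(k) + 1
  tibble::tibble(
    count = 0:W,
    proportion = tabulate(counts + 1L, nbins = W + 1) / length(counts)
  )
}

#' Boxplot summary for a complementary pair (Analysis 4)
#'
#' Five-number summary of the pooled per-block counts of a complementary
#' pair: median, linear-interpolation quartiles (R quantile type 7), whiskers
#' at the most extreme points within 1.5 IQR of the quartiles, and the
#' outliers beyond them. The count distributions are strongly right-skewed,
#' which is why the median — not the mean — is the summary under which
#' human and unbiased data agree.
#'
#' @inheritParams pair_count_distribution
#' @return A one-row tibble with columns `pair`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, and `outliers` (list column).
#' @examples
#' pair_summary(generate_bernoulli(100, seed = 1), "0001")
#' @export
pair_summary <- function(data, pair, k = 4) {
  counts <- pooled_pair_counts(data, pair, k)
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- counts[counts >= lo_fence & counts <= hi_fence]
  tibble::tibble(
    pair = paste(resolve_pair(pair), collapse = "/"),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    whisker_low = min(inside),
    whisker_high = max(inside),
    outliers = list(sort(counts[counts < lo_fence | counts > hi_fence]))
  )
}

pooled_pair_counts <- function(data, pair, k) {
  pair <- resolve_pair(pair)
  if (nchar(pair[1]) != k) {
    stop("pair words have length ", nchar(pair[1]), " but k = ", k, ".",
         call. = FALSE)
  }
  wv <- dataset_window_values(data, k)
  c(rowSums(wv == word_value(pair[1])), rowSums(wv == word_value(pair[2])))
}

#' Root-mean-square error between two occurrence-rate tables
#'
#' RMSE over the `2^k` words between an observed rate table and a reference
#' table — the dependent variable used to score how closely a generated
#' dataset matches the sliding-window profile of an unbiased source.
#'
#' @param observed,reference Data frames with columns `word` and a rate
#'   column (`rate` by default), or named numeric vectors keyed by word.
#'   Their word sets must match.
#' @param col Name of the value column when data frames are supplied.
#' @return A single nonnegative number.
#' @examples
#' obs <- occurrence_rate(generate_bernoulli(360, seed = 1))
#' rmse_to_reference(obs, tu_reference())
#' @export
rmse_to_reference <- function(observed, reference, col = "rate") {
  m <- align_rates(observed, reference, col)
  sqrt(mean((m$a - m$b)^2))
}

#' Pearson correlation between two occurrence-rate tables
#'
#' Correlation across the `2^k` words of two rate vectors, the statistic used
#' to ask how well one source's occurrence-rate profile tracks another's.
#'
#' @inheritParams rmse_to_reference
#' @return A correlation in `[-1, 1]`. Errors if either vector has zero
#'   variance (the correlation is undefined).
#' @examples
#' a <- occurrence_rate(generate_bernoulli(360, seed = 1))
#' rate_correlation(a, tu_reference())
#' @export
rate_correlation <- function(observed, reference, col = "rate") {
  m <- align_rates(observed, reference, col)
  if (length(m$a) < 3) {
    stop("need at least 3 words to correlate.", call. = FALSE)
  }
  if (stats::sd(m$a) == 0 || stats::sd(m$b) == 0) {
    stop("correlation undefined: a rate vector has zero variance.",
         call. = FALSE)
  }
  stats::cor(m$a, m$b)
}

#' Per-participant RMSE to a reference rate table
#'
#' Computes each participant's (and phase's) occurrence-rate vector from
#' their own blocks and its RMSE to `reference` — the per-subject dependent
#' variable for pre/post comparisons.
#'
#' @inheritParams average_frequency
#' @param reference A rate table as in [rmse_to_reference()]; typically
#'   [tu_reference()].
#' @return A tibble with columns `participant`, `phase`, `n_blocks`, `rmse`.
#' @examples
#' coh <- generate_cohort(participants = 4, blocks = 10, seed = 1)
#' participant_rmse(coh, tu_reference())
#' @export
participant_rmse <- function(data, reference, k = 4) {
  data <- validate_dataset(data)
  wv <- dataset_window_values(data, k)
  grp <- interaction(data$participant, data$phase, drop = TRUE, sep = "\r")
  gid <- as.integer(grp)
  sizes <- tabulate(gid, nbins = nlevels(grp))
  words <- all_words(k)
  rates <- vapply(seq_along(words), function(i) {
    rowsum(as.numeric(rowSums(wv == (i - 1L)) > 0), gid)[, 1]
  }, numeric(nlevels(grp)))
  rates <- matrix(rates, nrow = nlevels(grp)) / sizes
  ref <- align_rates(
    tibble::tibble(word = words, rate = rep(0, length(words))),
    reference, "rate"
  )$b
  keys <- strsplit(levels(grp), "\r", fixed = TRUE)
  tibble::tibble(
    participant = vapply(keys, `[`, character(1), 1),
    phase = vapply(keys, `[`, character(1), 2),
    n_blocks = sizes,
    rmse = sqrt(rowMeans((rates - matrix(ref, nrow = nrow(rates),
                                         ncol = length(ref),
                                         byrow = TRUE))^2))
  )
}

# normalise a rate table (tibble or named vector) and align two of them by
# word, erroring on mismatched word sets
align_rates <- function(observed, reference, col) {
  one <- function(x, label) {
    if (is.data.frame(x)) {
      if (!all(c("word", col) %in% names(x))) {
        stop(label, " must have columns `word` and `", col, "`.",
             call. = FALSE)
      }
      stats::setNames(x[[col]], x$word)
    } else if (is.numeric(x) && !is.null(names(x))) {
      x
    } else {
      stop(label, " must be a data frame or a named numeric vector.",
           call. = FALSE)
    }
  }
  a <- one(observed, "`observed`")
  b <- one(reference, "`reference`")
  if (!setequal(names(a), names(b)) || anyDuplicated(names(a)) ||
      anyDuplicated(names(b))) {
    stop("word sets of the two rate tables do not match.", call. = FALSE)
  }
  ord <- sort(names(a))
  list(a = unname(a[ord]), b = unname(b[ord]))
}
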