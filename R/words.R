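#' Binary words of length k
#'
#' A *word* is a string over `{0,1}` of length `k` (default 4), the unit
#' counted by the sliding window. `all_words()` enumerates the `2^k` words in
#' increasing binary value; `word_complement()` flips every symbol;
#' `word_reverse()` reverses it. A word is never equal to its complement, so
#' the `2^k` words partition into `2^(k-1)` complementary pairs, enumerated by
#' [complementary_pairs()].
#'
#' @param k Word (window) length, a positive integer.
#' @param word A binary word, e.g. `"0001"`.
#' @return `all_words()` a character vector of length `2^k`;
#'   `word_complement()` and `word_reverse()` a single word;
#'   `word_value()` the integer the word encodes (most significant bit first).
#' @examples
#' all_words(2)
#' word_complement("0001")
#' @export
all_words <- function(k) {
  check_k(k)
  vapply(0:(2^k - 1), int_to_word, character(1), k = k)
}

#' @rdname all_words
#' @export
word_complement <- function(word) {
  check_word(word)
  chartr("01", "10", word)
}

#' @rdname all_words
#' @export
word_reverse <- function(word) {
  check_word(word)
  paste(rev(strsplit(word, "")[[1]]), collapse = "")
}

#' @rdname all_words
#' @export
word_value <- function(word) {
  check_word(word)
  strtoi(word, base = 2L)
}

#' Complementary word pairs
#'
#' The canonical representative of each pair is the word starting with 0; its
#' partner is the bitwise complement. Pair-level statistics (Analyses 3 and 4)
#' pool counts over the two members because an unbiased source treats them
#' symmetrically.
#'
#' @param k Word length.
#' @return A tibble with columns `pair` (label `"w/complement"`), `word`, and
#'   `complement`, one row per pair, `2^(k-1)` rows.
#' @examples
#' complementary_pairs(3)
#' @export
complementary_pairs <- function(k) {
  check_k(k)
  words <- all_words(k)
  lead <- words[startsWith(words, "0")]
  tibble::tibble(
    pair = paste(lead, chartr("01", "10", lead), sep = "/"),
    word = lead,
    complement = chartr("01", "10", lead)
  )
}

# Resolve a user-supplied pair (one word, both words, or "w/wbar" label) to
# its two members, erroring unless they are bitwise complements.
resolve_pair <- function(pair) {
  if (length(pair) == 1 && grepl("/", pair, fixed = TRUE)) {
    pair <- strsplit(pair, "/", fixed = TRUE)[[1]]
  }
  if (length(pair) == 1) {
    check_word(pair)
    pair <- c(pair, chartr("01", "10", pair))
  }
  if (length(pair) != 2) {
    stop("`pair` must be one word, two words, or a \"w/complement\" label.",
         call. = FALSE)
  }
  check_word(pair[1]); check_word(pair[2])
  if (chartr("01", "10", pair[1]) != pair[2]) {
    stop("words ", pair[1], " and ", pair[2], " are not bitwise complements.",
         call. = FALSE)
  }
  pair
}

int_to_word <- function(v, k) {
  paste(as.integer(bitwAnd(bitwShiftR(v, (k - 1):0), 1L)), collapse = "")
}

check_word <- function(word) {
  if (length(word) != 1 || !is.character(word) || !grepl("^[01]+$", word)) {
    stop("a word must be a single string over {0,1}, got: ",
         paste(format(word), collapse = ", "), call. = FALSE)
  }
  invisible(word)
}

check_k <- function(k) {
  if (length(k) != 1 || !is.numeric(k) || k < 1 || k != round(k)) {
    stop("`k` must be a single positive integer.", call. = FALSE)
  }
  invisible(as.integer(k))
}

check_prob <- function(p, name) {
  if (length(p) != 1 || !is.numeric(p) || is.na(p) || p < 0 || p > 1) {
    stop("`", name, "` must be a single probability in [0, 1].", call. = FALSE)
  }
  invisible(p)
}
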