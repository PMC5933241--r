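#' Build a sequence dataset
#'
#' A *sequence dataset* is a tibble with one row per block and columns
#' `participant`, `condition`, `phase`, `block_index`, and `block` (the digit
#' string). Blocks are fixed-length strings over `{0,1}`; the sliding window
#' never crosses a block boundary, so the block is the unit of analysis
#' throughout the package (the behavioural experiments paused the source every
#' 20 digits, which is why a 600-digit session decomposes into 30 independent
#' 20-bit blocks).
#'
#' @param blocks Character vector of equal-length binary strings.
#' @param participant,condition,phase Label columns, recycled across blocks.
#'   `condition` is conventionally one of `"silent"`, `"tones"`, `"TU"`,
#'   `"synthetic"`; `phase` one of `"pre"`, `"post"`, `"observe"`,
#'   `"generate"`, but any labels are accepted.
#' @param block_index Integer index of each block within its participant and
#'   phase; defaults to position within each participant/phase group.
#' @return A tibble with the five dataset columns.
#' @examples
#' sequence_dataset(c("01010101010101010101", "00000000000000000000"))
#' @export
sequence_dataset <- function(blocks,
                             participant = "P01",
                             condition = "synthetic",
                             phase = "generate",
                             block_index = NULL) {
  if (length(blocks) == 0) stop("`blocks` must be nonempty.", call. = FALSE)
  data <- tibble::tibble(
    participant = as.character(participant),
    condition = as.character(condition),
    phase = as.character(phase),
    block = as.character(blocks)
  )
  if (is.null(block_index)) {
    data <- data |>
      dplyr::group_by(.data$participant, .data$phase) |>
      dplyr::mutate(block_index = dplyr::row_number()) |>
      dplyr::ungroup()
  } else {
    data$block_index <- as.integer(block_index)
  }
  data <- data[, c("participant", "condition", "phase", "block_index", "block")]
  validate_dataset(data)
}

#' Validate a sequence dataset
#'
#' Checks the column contract, that every block is a string over `{0,1}` of
#' one shared length, and that block indices are unique within participant and
#' phase. Called internally by every analysis entry point; exported because it
#' is useful after hand-editing a dataset.
#'
#' @param data A data frame with columns `participant`, `condition`, `phase`,
#'   `block_index`, `block`.
#' @return The dataset, invisibly usable, as a tibble.
#' @export
validate_dataset <- function(data) {
  need <- c("participant", "condition", "phase", "block_index", "block")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("dataset has no blocks.", call. = FALSE)
  bad <- which(!grepl("^[01]+$", data$block))
  if (length(bad) > 0) {
    stop("block(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " contain symbols outside {0,1}.", call. = FALSE)
  }
  n <- nchar(data$block)
  if (length(unique(n)) != 1) {
    stop("all blocks must share one length; found lengths ",
         paste(sort(unique(n)), collapse = ", "), ".", call. = FALSE)
  }
  dup <- data |>
    dplyr::count(.data$participant, .data$phase, .data$block_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated block_index within participant/phase (e.g. participant ",
         dup$participant[1], ", phase ", dup$phase[1], ", index ",
         dup$block_index[1], ").", call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Sliding-window word counts for one block
#'
#' Slides a length-`k` window one symbol at a time through a block of length
#' `n` and counts, for each of the `2^k` words, how many of the `n - k + 1`
#' overlapping windows equal it. Windows never cross the block boundary.
#'
#' @param block A single binary string.
#' @param k Window length, `k <= nchar(block)`.
#' @return A tibble with columns `word` and `count`; counts sum to
#'   `n - k + 1`.
#' @examples
#' count_word_occurrences("01010101010101010101", k = 4)
#' @export
count_word_occurrences <- function(block, k = 4) {
  if (length(block) != 1 || !grepl("^[01]+$", block)) {
    stop("`block` must be a single string over {0,1}.", call. = FALSE)
  }
  k <- check_k(k)
  n <- nchar(block)
  if (k > n) {
    stop("window length k = ", k, " exceeds block length n = ", n, ".",
         call. = FALSE)
  }
  wv <- window_values(digit_matrix(block, n), k)
  tibble::tibble(
    word = all_words(k),
    count = tabulate(as.vector(wv) + 1L, nbins = 2^k)
  )
}

#' Read and write sequence datasets
#'
#' The file format is plain text, one block per line, symbol-per-character
#' with no separators. Canonical symbols are `0`/`1`; `H`/`T` are accepted on
#' read (the coin-flip cover story) and mapped `H -> 1`, `T -> 0`. An optional
#' manifest CSV with columns `participant,condition,phase,block_index,row`
#' attaches labels by line number (`row`); without one, default labels are
#' used.
#'
#' @param path Path of the sequence file.
#' @param manifest Path of the manifest CSV, or `NULL`.
#' @return `read_dataset()` returns a sequence dataset tibble;
#'   `write_dataset()` returns `path` invisibly after writing the sequence
#'   file and its manifest (`<path>.manifest.csv` by default).
#' @examples
#' tmp <- tempfile(fileext = ".txt")
#' d <- sequence_dataset(c("01100", "00111"))
#' write_dataset(d, tmp)
#' identical(read_dataset(tmp, paste0(tmp, ".manifest.csv")), d)
#' @export
read_dataset <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop("file ", path, " has no blocks.", call. = FALSE)
  lines <- chartr("HT", "10", lines)
  bad <- which(!grepl("^[01]+$", lines))
  if (length(bad) > 0) {
    stop("line ", bad[1], " of ", path,
         " contains symbols outside {0,1,H,T}.", call. = FALSE)
  }
  n <- nchar(lines)
  if (length(unique(n)) != 1) {
    ragged <- which(n != n[1])[1]
    stop("ragged block lengths in ", path, ": line ", ragged, " has ",
         n[ragged], " symbols where line 1 has ", n[1], ".", call. = FALSE)
  }
  if (is.null(manifest)) {
    return(sequence_dataset(lines))
  }
  man <- readr::read_csv(manifest, col_types = readr::cols(
    participant = readr::col_character(),
    condition = readr::col_character(),
    phase = readr::col_character(),
    block_index = readr::col_integer(),
    row = readr::col_integer()
  ))
  if (nrow(man) != length(lines)) {
    stop("manifest has ", nrow(man), " rows for ", length(lines), " blocks.",
         call. = FALSE)
  }
  man <- man[order(man$row), ]
  validate_dataset(tibble::tibble(
    participant = man$participant,
    condition = man$condition,
    phase = man$phase,
    block_index = man$block_index,
    block = lines[man$row]
  ))
}

#' @param data A sequence dataset.
#' @rdname read_dataset
#' @export
write_dataset <- function(data, path, manifest = paste0(path, ".manifest.csv")) {
  data <- validate_dataset(data)
  writeLines(data$block, path)
  readr::write_csv(
    tibble::tibble(
      participant = data$participant,
      condition = data$condition,
      phase = data$phase,
      block_index = data$block_index,
      row = seq_len(nrow(data))
    ),
    manifest
  )
  invisible(path)
}

# ---- internal digit/window machinery ---------------------------------------

# Blocks (equal-length binary strings) -> integer 0/1 matrix, one row per
# block. charToRaw on the collapsed string avoids a per-block strsplit.
digit_matrix <- function(blocks, n = nchar(blocks[1])) {
  matrix(as.integer(charToRaw(paste(blocks, collapse = ""))) - 48L,
         nrow = length(blocks), ncol = n, byrow = TRUE)
}

digits_to_blocks <- function(dm) {
  do.call(paste0, as.data.frame(dm))
}

# Digit matrix -> matrix of window word values (rows = blocks, cols = the
# n-k+1 window offsets), each value in 0..2^k-1, most significant bit first.
window_values <- function(dm, k) {
  n <- ncol(dm)
  if (k > n) {
    stop("window length k = ", k, " exceeds block length n = ", n, ".",
         call. = FALSE)
  }
  pw <- 2^((k - 1):0)
  nb <- nrow(dm)
  out <- vapply(seq_len(n - k + 1), function(s) {
    as.integer(dm[, s:(s + k - 1), drop = FALSE] %*% pw)
  }, integer(nb))
  matrix(out, nrow = nb)
}

dataset_window_values <- function(data, k) {
  data <- validate_dataset(data)
  k <- check_k(k)
  window_values(digit_matrix(data$block), k)
}
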