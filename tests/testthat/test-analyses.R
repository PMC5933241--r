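test_that("average frequency handles degenerate datasets exactly", {
  one <- sequence_dataset(strrep("0", 20))
  f <- average_frequency(one)
  expect_equal(f$frequency[f$word == "0000"], 17)
  expect_equal(sum(f$frequency), 17)

  two <- sequence_dataset(c(strrep("0", 20), strrep("1", 20)))
  f2 <- average_frequency(two)
  expect_equal(f2$frequency[f2$word == "0000"], 8.5)
  expect_equal(f2$frequency[f2$word == "1111"], 8.5)
})

test_that("occurrence rate matches block-wise definitions", {
  alt <- sequence_dataset(strrep("01", 10))
  r <- occurrence_rate(alt)
  expect_equal(r$rate[r$word %in% c("0101", "1010")], c(1, 1))
  expect_equal(sum(r$rate), 2)

  zeros <- sequence_dataset(rep(strrep("0", 20), 3))
  rz <- occurrence_rate(zeros)
  expect_equal(rz$rate[rz$word == "0000"], 1)
  expect_equal(sum(rz$rate), 1)
})

test_that("large unbiased samples approach the exact reference", {
  d <- generate_bernoulli(100000, seed = 811)
  f <- average_frequency(d)
  # Monte-Carlo error on a mean count at 1e5 blocks is ~0.003
  expect_true(all(abs(f$frequency - 1.0625) < 0.02))
  r <- occurrence_rate(d)
  tu <- tu_reference()
  expect_true(all(abs(r$rate - tu$rate) < 0.01))
})

test_that("finite TU cohorts stay inside their own replicate bounds", {
  d <- generate_bernoulli(360, seed = 271)
  r <- occurrence_rate(d)
  ci <- tu_replicate_ci(360, reps = 300, seed = 272)
  m <- dplyr::left_join(r, ci, by = "word")
  # marginal 95% bands: a handful of the 16 words may fall just outside
  expect_lte(sum(m$rate < m$lower | m$rate > m$upper), 2)
})

test_that("pair distributions pool complements and keep their expectation", {
  one <- sequence_dataset(strrep("0", 20))
  pd <- pair_count_distribution(one, "0000")
  expect_equal(pd$proportion[pd$count == 17], 0.5)
  expect_equal(pd$proportion[pd$count == 0], 0.5)
  expect_equal(sum(pd$proportion), 1)
  expect_error(pair_count_distribution(one, c("0000", "1110")), "complement")

  # expectation of the pooled distribution equals the mean of the two
  # per-word average frequencies, on random data
  withr::local_seed(300)
  d <- generate_markov(40, switch_rate = 0.65)
  f <- average_frequency(d)
  for (p in c("0000", "0011", "0101")) {
    pd <- pair_count_distribution(d, p)
    expect_equal(
      sum(pd$count * pd$proportion),
      mean(f$frequency[f$word %in% c(p, word_complement(p))])
    )
  }
})

test_that("pair summaries use linear-interpolation quartiles", {
  # pooled counts [0, 0, 1, 2]: two blocks, pair counted per member
  d <- sequence_dataset(c("00110", "01100"))
  s <- pair_summary(d, "0011", k = 4)
  pooled <- c(
    vapply(d$block, naive_word_count, numeric(1), word = "0011"),
    vapply(d$block, naive_word_count, numeric(1), word = "1100")
  )
  expect_equal(s$median, unname(stats::quantile(pooled, 0.5)))
  expect_equal(s$q1, unname(stats::quantile(pooled, 0.25)))

  # constant pooled counts give a zero IQR
  const <- sequence_dataset(rep(strrep("0", 20), 4))
  sc <- pair_summary(const, "0101")
  expect_equal(sc$q3 - sc$q1, 0)
  expect_equal(sc$median, 0)
  # pooling alternation blocks mixes the two member counts (9 and 8)
  alt <- sequence_dataset(rep(strrep("01", 10), 4))
  sa <- pair_summary(alt, "0101")
  expect_equal(sa$median, 8.5)
})

test_that("exact pair medians rank near-runs above runs", {
  # from the exact count distributions: the pooled pair distribution of a
  # complementary pair equals either member's distribution, so the median
  # can be read off the exact CDF
  med <- function(word) {
    d <- exact_count_distribution(word, 20)
    d$count[which(cumsum(d$probability) >= 0.5)[1]]
  }
  expect_gte(med("0001"), med("0000"))
})

test_that("rmse and correlation follow their formulas", {
  tu <- tu_reference()
  expect_equal(rmse_to_reference(tu, tu), 0)
  shifted <- dplyr::mutate(tu, rate = rate + 0.1)
  expect_equal(rmse_to_reference(shifted, tu), 0.1)

  # all-zero generator versus exact reference, by direct expansion
  zeros <- occurrence_rate(sequence_dataset(strrep("0", 20)))
  byhand <- sqrt(sum((zeros$rate - tu$rate)^2) / 16)
  expect_equal(rmse_to_reference(zeros, tu), byhand)

  expect_equal(rate_correlation(tu, tu), 1)
  affine <- dplyr::mutate(tu, rate = 0.2 + 0.5 * rate)
  expect_equal(rate_correlation(affine, tu), 1)

  # three-point hand calculation
  a <- c(w1 = 0.1, w2 = 0.2, w3 = 0.4)
  b <- c(w1 = 0.2, w2 = 0.3, w3 = 0.8)
  byhand_r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(rate_correlation(a, b), byhand_r)

  expect_error(rate_correlation(c(w1 = 1, w2 = 1, w3 = 1), a), "variance")
  expect_error(rmse_to_reference(a, c(w1 = 0.1, w4 = 0.2, w3 = 0.1)),
               "word sets")
})

test_that("complementing every block permutes word stats and fixes pair stats", {
  withr::local_seed(52)
  d <- generate_boost(50, pair = "0001", beta = 0.8)
  dc <- dplyr::mutate(d, block = chartr("01", "10", block))
  f <- average_frequency(d)
  fc <- average_frequency(dc)
  expect_equal(
    fc$frequency[match(vapply(f$word, word_complement, character(1)),
                       fc$word)],
    f$frequency
  )
  for (p in c("0000", "0001")) {
    expect_equal(pair_count_distribution(d, p),
                 pair_count_distribution(dc, p))
  }
})

test_that("TU cohorts of study size correlate tightly with the exact rates", {
  # at 360 blocks the sampled-vs-exact correlation is typically ~0.97
  # (median), the calibration against which an observed human correlation
  # of similar size reads as genuine similarity to a random source
  tu <- tu_reference()
  withr::local_seed(606)
  rs <- vapply(1:20, function(i) {
    rate_correlation(occurrence_rate(generate_bernoulli(360)), tu)
  }, numeric(1))
  expect_gt(stats::median(rs), 0.95)
  expect_gt(min(rs), 0.85)
})

test_that("per-participant rmse isolates each participant's blocks", {
  tu <- tu_reference()
  d <- dplyr::bind_rows(
    sequence_dataset(rep(strrep("0", 20), 3), participant = "A"),
    generate_bernoulli(30, seed = 77, participant = "B")
  )
  pr <- participant_rmse(d, tu)
  zeros <- occurrence_rate(sequence_dataset(strrep("0", 20)))
  expect_equal(pr$rmse[pr$participant == "A"],
               rmse_to_reference(zeros, tu))
  expect_equal(pr$rmse[pr$participant == "B"],
               rmse_to_reference(
                 occurrence_rate(dplyr::filter(d, participant == "B")), tu))
  expect_equal(pr$n_blocks, c(3, 30))
})
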