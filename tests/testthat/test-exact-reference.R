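test_that("single-window cases have closed-form probabilities", {
  expect_equal(exact_occurrence_rate("0", 1), 0.5)
  expect_equal(exact_occurrence_rate("0000", 4), 1 / 16)
  d <- exact_count_distribution("0000", 4)
  expect_equal(d$probability, c(15 / 16, 1 / 16))
})

test_that("enumeration and automaton paths agree to high precision", {
  # every word at k = 3 and 4 for the full 20-bit block; the larger window
  # lengths at a shorter block keep the 2^n scan cheap
  cases <- rbind(
    expand.grid(k = 3:4, n = 20),
    expand.grid(k = 5:6, n = 14)
  )
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; n <- cases$n[i]
    for (w in all_words(k)) {
      da <- exact_count_distribution(w, n, "automaton")
      de <- exact_count_distribution(w, n, "enumeration")
      expect_equal(da$probability, de$probability, tolerance = 1e-13)
      expect_equal(sum(da$probability), 1, tolerance = 1e-12)
      expect_equal(sum(da$count * da$probability), (n - k + 1) / 2^k,
                   tolerance = 1e-12)
    }
  }
})

test_that("exact 20-bit values match the frozen enumeration constants", {
  expect_equal(exact_occurrence_rate("0000", 20), EXACT_RATE_0000_N20,
               tolerance = 1e-12)
  expect_equal(exact_occurrence_rate("0001", 20), EXACT_RATE_0001_N20,
               tolerance = 1e-12)
  d <- exact_count_distribution("0000", 20)
  expect_equal(d$probability[1], EXACT_MASS0_0000_N20, tolerance = 1e-12)
  expect_equal(1.0625, sum(d$count * d$probability), tolerance = 1e-12)
})

test_that("automaton transitions follow the failure function", {
  a <- build_word_automaton("00")
  # state after reading "01": match of "0" then mismatch resets to 0
  s <- 0
  for (c in c(0, 1)) s <- a$transitions[s + 1, c + 1]
  expect_equal(s, 0)
  s <- 0
  for (c in c(0, 0)) s <- a$transitions[s + 1, c + 1]
  expect_equal(s, 2)

  # complementing the word swaps the symbol columns of the automaton
  for (w in c("0010", "0110", "010")) {
    t1 <- build_word_automaton(w)$transitions
    t2 <- build_word_automaton(word_complement(w))$transitions
    expect_equal(unname(t1), unname(t2[, 2:1]))
  }
})

test_that("tu_reference orders words as the account predicts", {
  tu <- tu_reference(n = 20, k = 4)
  runs <- tu$rate[tu$word %in% c("0000", "1111")]
  alts <- tu$rate[tu$word %in% c("0101", "1010")]
  rest <- tu$rate[!tu$word %in% c("0000", "1111", "0101", "1010")]
  expect_equal(runs[1], runs[2])
  expect_equal(alts[1], alts[2])
  expect_lt(max(runs), min(alts))
  expect_lt(max(alts), min(rest))
  # complementary words share all exact statistics
  pr <- complementary_pairs(4)
  for (i in seq_len(nrow(pr))) {
    expect_equal(tu$rate[tu$word == pr$word[i]],
                 tu$rate[tu$word == pr$complement[i]])
    expect_equal(tu$mass_at_0[tu$word == pr$word[i]],
                 tu$mass_at_0[tu$word == pr$complement[i]])
  }
  expect_equal(tu$rate, 1 - tu$mass_at_0)
})

test_that("replicate confidence bounds behave like percentile intervals", {
  ci <- tu_replicate_ci(n_blocks = 360, reps = 200, seed = 31)
  exact <- tu_reference(n = 20, k = 4)
  # the interval for each word brackets the exact rate at this sample size
  m <- dplyr::left_join(ci, exact, by = "word")
  expect_true(all(m$lower <= m$rate & m$rate <= m$upper))
  expect_true(all(m$lower <= m$median & m$median <= m$upper))

  # expected-frequency metric brackets the analytic 1.0625
  cif <- tu_replicate_ci(n_blocks = 360, reps = 100, seed = 32,
                         metric = "average_frequency")
  expect_true(all(cif$lower <= 1.0625 & 1.0625 <= cif$upper))

  # degenerate but valid interval at two replicates
  ci2 <- tu_replicate_ci(n_blocks = 30, reps = 2, seed = 33)
  expect_true(all(ci2$lower <= ci2$upper))
  expect_error(tu_replicate_ci(30, reps = 1), "at least 2")

  # reproducible under the same seed
  expect_identical(tu_replicate_ci(60, reps = 20, seed = 5),
                   tu_replicate_ci(60, reps = 20, seed = 5))
})

test_that("enumeration refuses impracticable and invalid inputs", {
  expect_error(exact_count_distribution("0000", 30, "enumeration"), "n <= 24")
  expect_error(exact_occurrence_rate("0000", 3), "exceeds")
})
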