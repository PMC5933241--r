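test_that("bernoulli generator honours extreme and neutral base rates", {
  expect_true(all(generate_bernoulli(5, base_rate = 1, seed = 1)$block ==
                    strrep("0", 20)))
  expect_true(all(generate_bernoulli(5, base_rate = 0, seed = 1)$block ==
                    strrep("1", 20)))
  expect_error(generate_bernoulli(5, base_rate = 1.2), "probability")

  # unbiased occurrence rates approach the exact reference
  r <- occurrence_rate(generate_bernoulli(50000, seed = 21))
  expect_true(all(abs(r$rate - tu_reference()$rate) < 0.015))
})

test_that("markov generator alternates, sticks, and neutralises at 0.5", {
  alt <- generate_markov(5, switch_rate = 1, seed = 2)
  expect_true(all(alt$block %in% c(strrep("01", 10), strrep("10", 10))))
  const <- generate_markov(5, switch_rate = 0, seed = 2)
  expect_true(all(const$block %in% c(strrep("0", 20), strrep("1", 20))))

  r <- occurrence_rate(generate_markov(50000, switch_rate = 0.5, seed = 23))
  expect_true(all(abs(r$rate - tu_reference()$rate) < 0.015))
})

test_that("boost generator reduces to unbiased at beta = 0.5", {
  r <- occurrence_rate(generate_boost(50000, pair = "0001", beta = 0.5,
                                      seed = 31))
  expect_true(all(abs(r$rate - tu_reference()$rate) < 0.015))
})

test_that("full boost forbids runs when the pair breaks them", {
  d <- generate_boost(2000, pair = "0001", beta = 1, seed = 41)
  r <- occurrence_rate(d)
  expect_equal(r$rate[r$word == "0000"], 0)
  expect_equal(r$rate[r$word == "1111"], 0)
})

test_that("partial boost shifts rates in the constructed direction", {
  r <- occurrence_rate(generate_boost(100000, pair = "0001", beta = 0.7,
                                      seed = 43))
  tu <- tu_reference()
  expect_gt(r$rate[r$word == "0001"], tu$rate[tu$word == "0001"])
  expect_lt(r$rate[r$word == "0000"], tu$rate[tu$word == "0000"])
})

test_that("boosting a pair equals de-boosting its twin, draw for draw", {
  # boosting (0000,1111) with beta assigns the same conditional digit law as
  # boosting (0001,1110) with 1 - beta, so a shared seed gives identical
  # datasets
  for (beta in c(0.2, 0.5, 0.9)) {
    expect_identical(
      generate_boost(200, pair = "0000", beta = beta, seed = 55)$block,
      generate_boost(200, pair = "0001", beta = 1 - beta, seed = 55)$block
    )
  }
})

test_that("generator output is bit-identical under a fixed seed", {
  expect_identical(generate_bernoulli(50, seed = 9),
                   generate_bernoulli(50, seed = 9))
  expect_identical(generate_markov(50, switch_rate = 0.7, seed = 9),
                   generate_markov(50, switch_rate = 0.7, seed = 9))
  expect_identical(generate_boost(50, beta = 0.8, seed = 9),
                   generate_boost(50, beta = 0.8, seed = 9))
})

test_that("complementing output digits mirrors the complementary process", {
  # P(0) = b complemented is distributed as P(0) = 1 - b: compare pooled
  # digit frequencies at matched seeds
  d <- generate_bernoulli(2000, base_rate = 0.3, seed = 61)
  ones <- mean(digit_matrix_prop(d))
  d2 <- generate_bernoulli(2000, base_rate = 0.7, seed = 62)
  expect_equal(1 - ones, mean(digit_matrix_prop(d2)), tolerance = 0.02)

  # boost generator: complementing blocks preserves the law exactly (the
  # boosted pair is closed under complement); check rate symmetry
  r <- occurrence_rate(generate_boost(50000, pair = "0001", beta = 0.7,
                                      seed = 63))
  pr <- complementary_pairs(4)
  for (i in seq_len(nrow(pr))) {
    expect_equal(r$rate[r$word == pr$word[i]],
                 r$rate[r$word == pr$complement[i]], tolerance = 0.03)
  }
})

test_that("warmup variants agree on conditioned positions", {
  # prepended warm-up conditions every retained digit; rates shift slightly
  # further from TU than the embedded variant at the boosted word
  re <- occurrence_rate(generate_boost(50000, beta = 0.9, seed = 71,
                                       warmup = "embedded"))
  rp <- occurrence_rate(generate_boost(50000, beta = 0.9, seed = 72,
                                       warmup = "prepended"))
  expect_gte(rp$rate[rp$word == "0001"] + 0.01, re$rate[re$word == "0001"])
  expect_error(generate_boost(10, pair = "01", n = 1), "exceeds")
})
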