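Package: windowrand
Title: Sliding-Window Subsequence Statistics and Generative Models of
    Binary Sequence Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing finite binary sequences through the
    sliding-window subsequence statistics used in the study of human
    randomness perception. Computes exact occurrence rates, expected
    frequencies and full count distributions of length-k words in
    length-n blocks under an unbiased Bernoulli source, by complete
    enumeration and by a pattern-matching automaton; provides seeded
    Bernoulli, Markov-switching and context-sensitive "boost"
    generators of binary blocks; measures how perturbing a random
    source degrades the match between its occurrence-rate profile and
    the unbiased reference; and fits the one-parameter boost model of
    human random sequence generation by Monte-Carlo lookup-table
    interpolation and residual minimisation, with synthetic cohort
    generators for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
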