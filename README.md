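# windowrand

Sliding-window subsequence statistics for finite binary sequences, and a
one-parameter generative model of human random-sequence production.

## The problem

People asked to "generate a random sequence of coin flips" produce output
whose subsequence *frequencies* deviate from an ideal Bernoulli(0.5) source
— runs underrepresented, alternations overrepresented — which is usually
read as bias in randomness perception. The sliding-window account reframes
the question: if experience of an unfolding sequence passes through a short
window of length *k* (≈ 4 outcomes) sliding one step at a time through a
finite block of length *n*, the natural statistics are per-block. For a
word *w* of length *k* in an unbiased block of length *n*:

- expected frequency per block: `(n − k + 1) / 2^k` — identical for every
  word (1.0625 at n = 20, k = 4);
- occurrence rate: `P(w occurs ≥ once among the n − k + 1 windows)` —
  sharply different across words even for a fair source. At n = 20 it is
  0.478 for `0000` but 0.746 for `0001`; a fair 20-bit block misses `0000`
  entirely 52.2% of the time.

The package computes these reference values exactly (full `2^n` enumeration
cross-checked by a Knuth–Morris–Pratt pattern-automaton propagation), runs
the block-level analyses (average frequency, occurrence rate, pooled
complementary-pair count histograms and boxplot summaries, RMSE and
correlation scoring), simulates perturbed sources (base-rate, Markov
switching), and implements the **boost model**: after a context equal to
the first k−1 symbols of a designated word (or its complement), the next
digit completes that word with probability β; in all other contexts it is
fair. β = 0.5 is exactly unbiased; boosting `0001/1110` with β > 0.5
breaks runs of three — the gambler's-fallacy signature in one parameter.
β is fitted to observed occurrence rates by Monte-Carlo lookup table
(21 grid points × 100,000 simulated blocks), per-word linear interpolation
and derivative-free RMSE minimisation. Seeded synthetic cohorts stand in
for human participants for parameter-recovery studies.

## Worked example

```r
library(windowrand)

# exact unbiased reference at n = 20, k = 4
tu <- tu_reference()
tu[tu$word %in% c("0000", "0001", "0101"), ]
#> # A tibble: 3 × 4
#>   word   rate expected_frequency mass_at_0
#>   <chr> <dbl>              <dbl>     <dbl>
#> 1 0000  0.478               1.06     0.522
#> 2 0001  0.746               1.06     0.254
#> 3 0101  0.643               1.06     0.357

# a synthetic "participant" cohort from the boost model, then recover beta
coh  <- generate_boost(100000, pair = "0001", beta = 0.7, seed = 1)
lk   <- build_beta_lookup("0001", sims_per_point = 100000, seed = 2)
fit  <- fit_beta(occurrence_rate(coh), lk)
glance(fit)
#> # A tibble: 1 × 4
#>   pair       beta    rmse n_words
#>   <chr>     <dbl>   <dbl>   <int>
#> 1 0001/1110 0.703 0.00157      16
```

The fitted β of 0.703 recovers the generating value of 0.70 to within the
procedure's ±0.02 tolerance, and the RMSE of 0.0016 sits at the lookup's
Monte-Carlo noise floor — the model fitting its own output about as well
as the simulation budget allows.
`tidy(fit)` returns per-word residuals; `autoplot(fit)` draws observed
points over the fitted rate profile. `run_pipeline("exp2-synthetic")`
writes the full CSV report bundle (analyses, fitted-β and residual tables
for all eight complementary pairs, pre and post phase) for a seeded
synthetic cohort.

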