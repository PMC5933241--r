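---
title: "Sliding-window subsequence statistics and the boost model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window subsequence statistics and the boost model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windowrand)
library(dplyr)
```

## The problem

When people are asked to produce a random binary sequence, the frequencies
of short subsequences in their output depart from the uniform frequencies an
ideal Bernoulli(0.5) source would produce in the long run: runs such as
`1111` are underrepresented, alternations overrepresented. The classical
reading is that human randomness perception is biased. The sliding-window
account reframes the comparison: people experience an unfolding sequence
through a short window of about four outcomes moving one symbol at a time
through a *finite* stretch of experience. Under that reading the natural
statistics are not long-run frequencies but per-block quantities — how often
does a length-`k` word occur among the `n - k + 1` windows of a length-`n`
block, and in what fraction of blocks does it occur at all?

These statistics are surprisingly non-uniform even for a perfectly unbiased
source. Every length-4 word has the same expected frequency per 20-bit
block, `(n - k + 1) / 2^k = 17/16 = 1.0625`, yet the probability that a
block contains the word at all differs sharply by word:

```{r exact}
tu <- tu_reference(n = 20, k = 4)
tu |> arrange(rate) |> head(4)
```

Runs (`0000`/`1111`, rate `r round(tu$rate[tu$word == "0000"], 4)`) occur in
fewer blocks than alternations (`0101`/`1010`), which occur in fewer blocks
than everything else. A block has a
`r round(100 * tu$mass_at_0[tu$word == "0000"], 1)`% chance of containing no
`0000` at all, but only a
`r round(100 * tu$mass_at_0[tu$word == "0001"], 1)`% chance of missing
`0001`. The package computes these reference values exactly, simulates the
generating processes that might mimic them, and fits a one-parameter
generative model of human production against them.

## Exact reference: two independent computation paths

`tu_reference()`, `exact_occurrence_rate()` and
`exact_count_distribution()` support two methods that check one another:

* **Full enumeration** scans all `2^n` blocks with a bit-parallel window
  comparison. It is exact by construction and practical to `n = 24`.
* **Automaton propagation** builds the Knuth–Morris–Pratt pattern automaton
  of the word (`build_word_automaton()`; states are matched-prefix lengths
  `0..k`, transitions follow the failure function) and propagates the joint
  distribution of (state, match count) for `n` unbiased steps. It is exact
  up to floating-point accumulation and linear in `n`, so it also serves
  arbitrary block lengths.

The test suite asserts agreement of the two paths to at least 12
significant digits for every word at `k = 3, 4` with `n = 20` and
`k = 5, 6` at a shorter block. Counting is overlap-allowed throughout
(`000000` contains three occurrences of `0000`), and windows never cross a
block boundary — that convention is forced by the expected frequency
`17/16` per 20-bit block.

Finite samples of an unbiased source stray from these exact values;
`tu_replicate_ci()` quantifies how far, by simulating replicate datasets
(default 1,000) of a given size and taking percentile intervals of each
word's statistic. The percentile construction (R's type-7 linear
interpolation at 2.5% and 97.5%) is our choice; normal-approximation
intervals differ negligibly at these replicate counts. With only two
replicates the interval degenerates gracefully toward the min/max.

## The four block-level analyses

For any dataset — simulated or read from disk via `read_dataset()` —
the analysis functions compute:

1. `average_frequency()`: mean count per block, per word.
2. `occurrence_rate()`: proportion of blocks containing the word at least
   once, pooled over all blocks (a per-participant variant backs
   `participant_rmse()`).
3. `pair_count_distribution()`: the per-block count histogram pooled over a
   complementary pair, each block contributing one count for the word and
   one for its complement.
4. `pair_summary()`: median, type-7 linear-interpolation quartiles,
   1.5 IQR whiskers and outliers of the pooled counts. The quartile and
   whisker conventions are fixed and documented because the count
   distributions are strongly right-skewed — the reason the median, not the
   mean, is the summary under which human-like and unbiased data agree.

`rmse_to_reference()` and `rate_correlation()` score a rate table against a
reference across the `2^k` words. The reference for RMSE is the *exact*
rate vector, not a sampled replicate: the comparison target is the account's
expected occurrence rate, and using the exact value removes one layer of
Monte-Carlo noise.

A calibration worth recording: at 360 blocks, the correlation between a
simulated unbiased cohort's rates and the exact reference has median about
0.97 and 5th percentile about 0.93 (400 simulated cohorts). An observed
human correlation near .97 is therefore exactly what a genuinely
random-like producer of 360 blocks would show — while, as the perturbation
study below shows, even mildly biased sources fall well short of it.

## Generators and the boost model

`generate_bernoulli()` (base rate `base_rate = P(0)`), `generate_markov()`
(switch probability `switch_rate`) and `generate_boost()` are seeded and
bit-reproducible; digit draws consume the RNG stream position by position
across blocks. Blocks are independent — context never carries across a
block boundary, mirroring the enforced pauses between experimental blocks.

The boost model produces each block as follows: the first `k - 1` digits
are unbiased warm-up; thereafter, when the previous `k - 1` digits match
the prefix of the boosted word (or of its complement), the next digit
completes that word with probability `beta`; in every other context the
digit is fair. `beta = 0.5` is exactly the unbiased source. Boosting
`0001/1110` with `beta > 0.5` raises the probability that a run of three is
broken — the gambler's-fallacy signature expressed as a single parameter.

Two structural identities are exploited as cross-checks. Boosting
`0000/1111` with `beta` prescribes the identical conditional law as
boosting `0001/1110` with `1 - beta`, so paired simulations under a shared
seed are bit-identical — the twin-pair (sum-to-one) identity. And the
boosted pair is closed under 0/1 complement, so all generator laws are
complement-symmetric.

The warm-up is *embedded*: the `k - 1` warm-up digits are the first digits
of the 20-bit block itself, keeping blocks at exactly `n` digits. The
alternative (`warmup = "prepended"` — generate the warm-up, discard it, and
retain `n` conditioned digits) is available for sensitivity analysis; at
`k = 4` it shifts occurrence rates by at most a few thousandths.

## Fitting the boost parameter

`build_beta_lookup()` simulates the model at each grid value of `beta`
(default 0 to 1 in steps of 0.05) with 100,000 blocks per point and stores
the per-word occurrence rates; the Monte-Carlo standard error of a stored
rate is about 0.0016. `predict_rates()` interpolates the table per word,
piecewise-linearly — the table is smooth in `beta` and a finer grid is
available where needed. `fit_beta()` minimises the RMSE between an observed
rate vector and the interpolated prediction. Because the objective is
piecewise smooth with one piece per grid interval, the optimiser runs a
golden-section search on every interval and keeps the global argmin
(tolerance `1e-6` on `beta`); this dominates any single-start simplex on
this objective and satisfies the same argmin contract.

`fit_all_pairs()` repeats the fit for all eight complementary pairs against
one observed profile, building one independent lookup per pair
(`build_all_lookups()`); the twin-pair identity — fitted betas of twin
pairs summing to 1, with near-identical residuals — then cross-checks the
entire lookup/interpolation/optimisation chain. Parameter-recovery tests
fix the tolerances the procedure supports: recovery within ±0.02 from
100,000-block cohorts and ±0.05 from 2,160-block cohorts across
`beta` from 0.55 to 0.8.

## Perturbation study

`perturbation_curve()` asks how strongly a source must deviate from
fairness before its occurrence-rate profile stops correlating with the
unbiased reference. For each parameter value it simulates replicate
datasets (default 360 blocks, 1,000 replicates), correlates each
replicate's rates with the exact reference, and reports percentile
intervals. The comparator is the exact rate vector rather than a sampled
unbiased replicate: exact removes one noise source, and the choice is
recorded in the output. Replicates with zero-variance rate vectors
— possible at parameter extremes — have undefined correlations and are
excluded with a count (`n_undefined`). The decay is steep: at a base rate
or switch rate of 0.65 the entire correlation CI lies below the median
correlation of the unperturbed source.

## Synthetic cohorts

No public human dataset accompanies this design, so `generate_cohort()`
stands in: each participant contributes 30 boost-model blocks per phase,
with phase-level boost parameters defaulting to `beta_pre = 0.765` and
`beta_post = 0.62` — midpoints of the reported per-condition fits (0.76
and 0.77 pre-exposure, 0.63 and 0.61 post-exposure), since no pooled value
is reported. `spread` adds optional participant-level heterogeneity
(truncated normal betas); it defaults to 0 because the fitting procedure
being emulated estimates a single parameter per condition.

What the synthetic cohort does *not* emulate: individual differences in
window length, non-stationarity within a session, any effect of the
sound/silent manipulation (reported null), and every response-level detail
(timing, motor errors). Tests that pass on these cohorts therefore
validate the *pipeline* — generation, statistics, fitting, recovery — not
any claim about human data.

`generate_stimulus()` produces the 600-digit observed stream (30 unbiased
blocks), and `mimicry_comparison()` contrasts a generated dataset's rates
with (a) that specific stimulus sample and (b) the exact reference. Even an
ideal random generator usually matches the exact reference better than it
matches any particular 30-block stimulus, because the stimulus's own rates
carry sampling noise — the quantitative backbone of the argument that
post-exposure improvement is not mimicry.

## Numerical and scale choices

* Enumeration is capped at `n = 24` (memory ~64 MB of integers); the
  automaton path covers larger `n`.
* Default analyses use `n = 20`, `k = 4`; all statistics accept `k` from 2
  up (supplementary analyses use 3–6).
* Test-suite problem sizes: lookup tables at the full 100,000 simulations
  per grid point for acceptance-grade fits, 20,000 for unit-grade; the
  perturbation exclusion check runs 200 replicates per grid point; the
  pre/post cohort comparison uses 100 seeded repetitions of 72 × 30-block
  cohorts. These sizes keep each statistical assertion several standard
  errors away from its threshold.
* Ties in `fit_beta()` resolve to the first interval scanned (lower
  `beta`); in practice the twin-pair identity makes ties measure-zero.
* Degenerate inputs error early with named lines/fields: ragged sequence
  files, non-binary symbols, non-complementary pairs, out-of-range
  probabilities, `k > n`.

## Known limitations

* The exact 20-bit occurrence rate of `0000` is 0.47802 (52.198% mass at
  zero); these values are often quoted loosely as "around 0.47" and
  "around 53%". The package reports the exact values.
* The boost model boosts exactly one pair at one window length; multi-pair
  and multi-length boosting are out of scope by design.
* `fit_beta()` inherits lookup Monte-Carlo noise; at 100,000 simulations
  per point the induced uncertainty on a fitted `beta` is well under 0.01,
  but refitting with a fresh lookup seed will move estimates at that order.
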