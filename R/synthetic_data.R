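#' Synthetic participant cohorts from the boost model
#'
#' Generates a labelled cohort standing in for human participants: each
#' participant contributes `blocks` boost-model blocks per phase, with the
#' phase-specific boost parameter (`beta_pre`, `beta_post`). Defaults mirror
#' the behavioural study the package models: 72 participants, 30 blocks of
#' 20 digits per phase, pair `0001/1110`, and phase betas of 0.765 (pre) and
#' 0.62 (post) — midpoints of the per-condition fits reported for sequence
#' generation before and after exposure to a genuine random source.
#'
#' `spread > 0` adds optional participant heterogeneity: each participant's
#' beta is drawn from a normal with the phase mean and SD `spread`, truncated
#' to `[0, 1]`. The default is 0 (a single beta per phase, as in the fitting
#' procedure being emulated).
#'
#' @param participants Number of participants.
#' @param blocks Blocks per participant per phase.
#' @param n Block length.
#' @param pair Boosted pair.
#' @param beta_pre,beta_post Boost parameter per phase; drop a phase from
#'   `phases` to generate only one.
#' @param spread SD of inter-participant beta variation (default 0).
#' @param phases Phases to generate, a subset of `c("pre", "post")`.
#' @param condition Condition label for all blocks.
#' @param seed Optional integer seed.
#' @return A sequence dataset tibble with participant, phase and condition
#'   labels.
#' @examples
#' coh <- generate_cohort(participants = 3, blocks = 5, seed = 1)
#' dplyr::count(coh, participant, phase)
#' @export
generate_cohort <- function(participants = 72, blocks = 30, n = 20,
                            pair = "0001", beta_pre = 0.765,
                            beta_post = 0.62, spread = 0,
                            phases = c("pre", "post"),
                            condition = "synthetic", seed = NULL) {
  if (participants < 1 || blocks < 1) {
    stop("`participants` and `blocks` must be positive.", call. = FALSE)
  }
  if (spread < 0) stop("`spread` must be nonnegative.", call. = FALSE)
  phases <- match.arg(phases, several.ok = TRUE)
  pair <- resolve_pair(pair)
  phase_beta <- c(pre = beta_pre, post = beta_post)[phases]
  purrr::walk2(phase_beta, names(phase_beta),
               function(b, nm) check_prob(b, paste0("beta_", nm)))
  if (!is.null(seed)) withr::local_seed(seed)
  ids <- sprintf("P%02d", seq_len(participants))
  parts <- purrr::map(phases, function(ph) {
    betas <- rep(phase_beta[[ph]], participants)
    if (spread > 0) {
      betas <- pmin(1, pmax(0, stats::rnorm(participants, betas, spread)))
    }
    purrr::map(seq_len(participants), function(p) {
      dm <- boost_digits(blocks, n, pair, betas[p])
      tibble::tibble(
        participant = ids[p],
        condition = condition,
        phase = ph,
        block_index = seq_len(blocks),
        block = digits_to_blocks(dm)
      )
    }) |> dplyr::bind_rows()
  })
  validate_dataset(dplyr::bind_rows(parts))
}

#' Unbiased "presented stimulus" stream
#'
#' The random stream a participant observes: `blocks` unbiased 20-bit blocks
#' (30 blocks of 20 digits = 600 digits by default), labelled
#' `phase = "observe"`, `condition = "TU"`.
#'
#' @param blocks Number of blocks (default 30).
#' @param n Block length (default 20).
#' @param seed Optional integer seed.
#' @return A sequence dataset tibble.
#' @export
generate_stimulus <- function(blocks = 30, n = 20, seed = NULL) {
  generate_bernoulli(blocks, n = n, base_rate = 0.5, seed = seed,
                     participant = "stimulus", condition = "TU",
                     phase = "observe")
}

#' Mimicry versus account comparison
#'
#' Did a generator of sequences reproduce the *specific* stream it observed,
#' or the *general* statistics of a random source? Compares the generated
#' dataset's occurrence-rate profile against (a) the observed stimulus
#' stream's own sample profile and (b) the exact unbiased reference, by
#' RMSE. A generated set closer to the exact reference than to the stimulus
#' argues against mimicry: a finite stimulus's own rates are noisy, so even
#' an ideal random generator matches the ideal reference better than it
#' matches any particular 30-block sample.
#'
#' @param generated,stimulus Sequence datasets with the same block length.
#' @param k Window length.
#' @return A tibble of class `mimicry_comparison` with columns `reference`
#'   (`"stimulus"`, `"exact_tu"`) and `rmse`; the per-word rate profiles are
#'   attached as attribute `"rates"` (columns `word`, `generated`,
#'   `stimulus`, `exact`).
#' @examples
#' gen <- generate_bernoulli(30, seed = 2)
#' stim <- generate_stimulus(seed = 3)
#' mimicry_comparison(gen, stim)
#' @export
mimicry_comparison <- function(generated, stimulus, k = 4) {
  generated <- validate_dataset(generated)
  stimulus <- validate_dataset(stimulus)
  if (nchar(generated$block[1]) != nchar(stimulus$block[1])) {
    stop("generated and stimulus datasets have different block lengths.",
         call. = FALSE)
  }
  n <- nchar(generated$block[1])
  g <- occurrence_rate(generated, k)
  s <- occurrence_rate(stimulus, k)
  e <- tu_reference(n = n, k = k)
  out <- tibble::tibble(
    reference = c("stimulus", "exact_tu"),
    rmse = c(rmse_to_reference(g, s), rmse_to_reference(g, e))
  )
  attr(out, "rates") <- tibble::tibble(
    word = g$word, generated = g$rate, stimulus = s$rate, exact = e$rate
  )
  class(out) <- c("mimicry_comparison", class(out))
  out
}
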