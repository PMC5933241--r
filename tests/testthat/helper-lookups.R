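# Full-size lookup tables (21 grid points x 100,000 simulated blocks per
# point, the generative-model fitting conditions) are expensive, so the
# acceptance tests share one memoised set covering all eight pairs.
.lookup_cache <- new.env(parent = emptyenv())

shared_all_lookups <- function() {
  if (is.null(.lookup_cache$all)) {
    .lookup_cache$all <- windowrand::build_all_lookups(
      k = 4, sims_per_point = 1e5, seed = 8101
    )
  }
  .lookup_cache$all
}
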