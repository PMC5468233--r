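# One shared benchmark cohort for the heavyweight reproduction tests:
# 2 sets x 10 groups x 1,105 designs x 4 cellularities, simulated once.
.cohort_cache <- new.env(parent = emptyenv())

benchmark_cohort <- function() {
  if (is.null(.cohort_cache$rows)) {
    co <- suppressWarnings(simulate_cohort(seed = 101L, n_sets = 2L,
                                           n_groups = 10L))
    .cohort_cache$rows <- co$rows
  }
  .cohort_cache$rows
}
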