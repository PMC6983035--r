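# Shared fixtures built once per test run. The full-size cohort (18 + 18
# subjects, 25 pre-onset minutes) is expensive, so its feature table is
# cached and reused by every test that needs it.

.fixture_cache <- new.env(parent = emptyenv())

cohort_feature_table <- function() {
  if (is.null(.fixture_cache$table)) {
    recs <- simulate_cohort(18L, 18L, seed = 42L)
    .fixture_cache$table <- build_feature_table(recs, n_minutes = 25L,
                                                seed = 42L)
  }
  .fixture_cache$table
}

# a small cohort for structural tests: 3 + 3 subjects, 3 pre-onset minutes
small_cohort <- function(seed = 7L) {
  simulate_cohort(3L, 3L, seed = seed,
                  normal_cfg = synth_config("normal", duration_s = 90),
                  scd_cfg = synth_config("scd", duration_s = 5 * 60))
}
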