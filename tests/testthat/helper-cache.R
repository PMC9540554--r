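# Expensive simulation artefacts shared across acceptance test blocks.
# Everything is generated in code at test time; runs are cached per test
# session so that several blocks can interrogate the same steady state.

.test_cache <- new.env(parent = emptyenv())

# One deconstructed run at the published protocol: 5e5 iterations,
# steady-state window 2e5-5e5, Table-1 defaults, seed 1.
acceptance_run <- function() {
  if (is.null(.test_cache$run)) {
    p <- lv_params(n_iterations = 500000L, burn_in = 200000L, seed = 1L)
    .test_cache$run <- run_deconstructed_assembly(p)
  }
  .test_cache$run
}

acceptance_records <- function() {
  if (is.null(.test_cache$records)) {
    run <- acceptance_run()
    .test_cache$records <- lineage_metrics(run, run$params$burn_in)
  }
  .test_cache$records
}

acceptance_landscape <- function() {
  if (is.null(.test_cache$landscape))
    .test_cache$landscape <- rolling_fitness_curves(acceptance_records())
  .test_cache$landscape
}

# Two desk-scale full-model runs whose seed consumers start with base
# attack rates 100-fold apart, both on the aggressive side of the evolved
# steady state where selection responds fastest.
full_desk_runs <- function() {
  if (is.null(.test_cache$full)) {
    .test_cache$full <- list(
      low = run_full_assembly(lv_params(n_iterations = 1500L, seed = 11L,
                                        a_init = 10^-3.67)),
      high = run_full_assembly(lv_params(n_iterations = 1500L, seed = 12L,
                                         a_init = 10^-1.67)))
  }
  .test_cache$full
}
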