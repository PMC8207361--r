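# Shared reduced factorial grid for the result-structure tests: both
# preference modes and landscapes, K in {5, 40, 160}, all six fishing
# levels, 10 replicates, master seed 1. Computed once per test session and
# reused by every file that needs it.
.grid_cache <- new.env(parent = emptyenv())

reduced_grid_summaries <- function() {
  if (is.null(.grid_cache$summaries)) {
    sc <- scenario_grid(K = c(5, 40, 160))
    .grid_cache$summaries <- run_scenario_grid(sc, replicates = 10L,
                                               master_seed = 1L)
  }
  .grid_cache$summaries
}
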