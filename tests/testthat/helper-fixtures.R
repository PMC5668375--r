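# Shared fixtures, built in code at test time.

tbl1 <- bcr_params_table1()
stage1 <- bcr_params_first_stage()

# small cohort for fast simulator tests (same calibrated parent, thinned)
small_cohort <- synthetic_cohort(n_cells = 50, seed = 1)

# the reference-size cohort for acceptance-level checks
full_cohort <- synthetic_cohort(n_cells = 200, seed = 1)

viability_at <- function(death_times, t) {
  mean(is.na(death_times) | death_times > t)
}

# revalidate a params list after tweaking a field
validate_params_for_test <- function(p) do.call(bcr_params, as.list(unclass(p)))

# light GA config for cheap convex benchmarks
cheap_ga <- function(...) {
  ga_config(children_per_generation = 10, max_generations = 300, ...)
}
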