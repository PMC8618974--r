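# shared fixtures, built once per test run

growth_ref <- load_growth_reference()
registry <- load_equation_registry()

# small per-session cohort cache keyed by seed/mechanism
.cohorts <- new.env(parent = emptyenv())
cached_cohort <- function(seed = 1L, mechanism = "weir_exact", n = 257) {
  key <- paste(seed, mechanism, n)
  if (is.null(.cohorts[[key]]))
    .cohorts[[key]] <- generate_cohort(cohort_spec(n = n, seed = seed,
                                                   ree_mechanism = mechanism))
  .cohorts[[key]]
}

# a complete ventilated infant record: every equation applicable
infant_record <- function() {
  list(id = 1L, male = 1, female = 0, age = 0.5, weight = 7, height = 67,
       bmi = bmi(7, 67), mechanically_ventilated = 1,
       vo2 = 0.05, vco2 = 0.04, rq = 0.8)
}

# GA/MLP settings scaled down for test runtime (defaults are pop 50, gen 100)
fast_ga <- function(seed = 1L, ...)
  ga_config(population_size = 12L, generations = 8L, seed = seed, ...)
fast_mlp <- function(seed = 1L, ...)
  mlp_spec(max_epochs = 200L, n_restarts = 1L, seed = seed, ...)

constant_series <- function(vo2 = 0.09, vco2 = 0.07, ve = 2.2, n = 30)
  calorimetry_series(rep(vo2, n), rep(vco2, n), rep(ve, n))
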