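# Shared fixture builders for the test suite.

# Config with every sampling SD set to zero: PSA draws degenerate to the
# parameter means.
zero_sd_config <- function(config) {
  config$valuation$disability_weight$sd <- 0
  config$valuation$baseline_utility$sd <- 0
  config$valuation$teeth_per_case$sd <- 0
  config$costs$checkup_fee$sd <- 0
  config$costs$restoration_fee_per_tooth$sd <- 0
  config$costs$home_visit_travel$sd <- 0
  config
}

zero_sd_spec <- function(spec) {
  for (nm in intersect(names(spec$effect),
                       c("sd", "sd_deciduous", "sd_permanent"))) {
    spec$effect[[nm]] <- 0
  }
  spec
}

# A do-nothing intervention: zero preventive fractions, no visits, no
# screening.  Its arm must coincide with the comparator exactly.
null_intervention <- function() {
  spec <- intervention_spec("2b")
  spec$effect$pf_deciduous <- 0
  spec$effect$pf_permanent <- 0
  spec$effect$sd_deciduous <- 0
  spec$effect$sd_permanent <- 0
  spec$visits_per_year <- c(0, 0)
  spec
}

fixture_cohort_of <- function(id) fixture_config(id)$cohort

# Small custom cohort config on the synthetic schedules, for oracle and
# property tests.
small_config <- function(start_ages = c(6, 12), size = 1000,
                         horizon = 2, seed = 1,
                         scenario = "base_case",
                         include_hospitalisation = FALSE) {
  ages <- seq(0, ceiling(max(start_ages) + 12) + 1)
  model_config(
    cohort = cohort_spec(start_ages, size, 2 * size, "test cohort"),
    horizon_years = horizon,
    incidence = make_incidence_schedule(seed = seed, ages = ages),
    mortality = make_mortality_schedule(seed = seed, ages = ages),
    scenario = scenario,
    include_hospitalisation = include_hospitalisation)
}
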