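test_that("discounting follows the closed form with cycle 0 undiscounted", {
  expect_equal(discount(100, 0, 0.03), 100)
  expect_equal(discount(100, 2, 0), 100)
  expect_equal(discount(100, 2, 0.03), 100 / 1.03^2)
  expect_equal(discount(100, 2, 0.03), 94.2596, tolerance = 1e-6)
  expect_error(discount(100, 2, -0.01), "rate")
  expect_error(discount(100, -1, 0.03), "cycle_index")
})

test_that("single transitions match a hand-evaluated oracle", {
  # all mass dead: absorbing
  dead <- c(0, 0, 0, 500)
  step <- transition_step(dead, 0.1, 0.05, 0.01)
  expect_equal(unname(step$occupancy), dead)
  # no incidence, no mortality: identity
  occ <- c(700, 200, 50, 50)
  step <- transition_step(occ, 0, 0, 0, recovery = "until_treated")
  expect_equal(unname(step$occupancy[-1L]), occ[-1L])
  expect_equal(sum(step$occupancy), sum(occ))
  # hand-computed single step: 1000 caries-free, incidence 0.2 (deciduous),
  # mortality 0.01, one-cycle recovery:
  #   deaths 10; cases 1000*0.99*0.2 = 198; caries-free 1000*0.99*0.8 = 792
  step <- transition_step(c(1000, 0, 0, 0), 0.2, 0, 0.01)
  expect_equal(unname(step$occupancy), c(792, 198, 0, 10))
  expect_equal(step$cases_deciduous, 198)
  expect_equal(step$cases_permanent, 0)
  expect_error(transition_step(c(-1, 0, 0, 0), 0.1, 0, 0), "negative")
})

test_that("mass is conserved and the dead state never shrinks", {
  for (k in 1:30) {
    p <- withr::with_seed(k, {
      occ <- runif(4, 0, 1000)
      i <- runif(2, 0, 0.5)
      list(occ = occ, idec = i[1], iperm = i[2], m = runif(1))
    })
    for (rec in c("one_cycle", "until_treated")) {
      step <- transition_step(p$occ, p$idec, p$iperm, p$m, recovery = rec)
      expect_equal(sum(step$occupancy), sum(p$occ), tolerance = 1e-9)
      expect_gte(step$occupancy[["dead"]], p$occ[4])
      expect_true(all(step$occupancy >= 0))
      expect_equal(step$occupancy[["edentulous"]],
                   p$occ[3] * (1 - p$m))  # no edentulism inflow
    }
  }
})

test_that("cohort runs conserve mass at every cycle", {
  cfg <- fixture_config("2a")
  for (spec in list(NULL, intervention_spec("2a"))) {
    tr <- run_cohort(cfg, spec)$trace
    n_sub <- length(cfg$cohort$start_ages)
    alive_plus_dead <- tr$caries_free + tr$caries + tr$edentulous + tr$dead
    expect_equal(alive_plus_dead,
                 rep(cfg$cohort$size_low_income / n_sub, nrow(tr)),
                 tolerance = 1e-9)
  }
})

test_that("zero incidence yields zero cases and healthcare cost", {
  cfg <- small_config(start_ages = 6, size = 500, horizon = 2)
  cfg$incidence$rate_low_income <- cfg$incidence$rate_low_income * 0
  cfg$incidence$rate_general <- cfg$incidence$rate_general * 0
  tr <- run_cohort(cfg)
  expect_equal(tr$totals[["cases"]], 0)
  expect_equal(tr$totals[["cost_healthcare"]], 0)
  expect_equal(tr$totals[["decayed_teeth"]], 0)
})

test_that("a null intervention reproduces the comparator exactly", {
  cfg <- fixture_config("2b")
  comp <- run_cohort(cfg)
  arm <- run_cohort(cfg, null_intervention())
  expect_equal(arm$totals[["cases"]], comp$totals[["cases"]])
  expect_equal(arm$totals[["cost_total"]], comp$totals[["cost_total"]])
  inc <- incremental_outcomes(comp, arm)
  expect_equal(unname(inc$discounted), rep(0, 4))
  expect_equal(unname(inc$undiscounted), rep(0, 4))
})

test_that("the comparator trace is invariant to co-computed interventions", {
  cfg <- fixture_config("3")
  before <- run_cohort(cfg)
  invisible(run_cohort(cfg, intervention_spec("3")))
  after <- run_cohort(cfg)
  expect_identical(before, after)
})

test_that("engine totals equal the loop-based reference oracle", {
  cases <- list(
    list(cfg = small_config(start_ages = 0.5, size = 800, horizon = 2),
         id = "1a"),
    list(cfg = small_config(start_ages = 0.5, size = 800, horizon = 2),
         id = "1b"),
    list(cfg = small_config(start_ages = 6:12, size = 1000, horizon = 2),
         id = "2a"),
    list(cfg = small_config(start_ages = 6:12, size = 1000, horizon = 2),
         id = "2b"),
    list(cfg = small_config(start_ages = c(6, 12), size = 1000,
                            horizon = 2), id = "3"),
    list(cfg = small_config(start_ages = c(6, 12), size = 1000,
                            horizon = 2,
                            scenario = "other_healthcare_costs"),
         id = "3"),
    list(cfg = small_config(start_ages = 0.5, size = 900, horizon = 2,
                            scenario = "other_healthcare_costs",
                            include_hospitalisation = TRUE), id = "1a"))
  for (case in cases) {
    spec <- intervention_spec(case$id)
    for (arm in list(NULL, spec)) {
      got <- engine_totals_vec(run_cohort(case$cfg, arm))
      want <- unname(ref_cohort_totals(case$cfg, arm))
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("engine totals (%s, %s)", case$id,
                                   if (is.null(arm)) "comparator" else "arm"))
    }
  }
})

test_that("extending the horizon past exhausted rates changes nothing", {
  ages <- seq(0, 15, by = 0.5)
  shape6 <- function(a) ifelse(a < 6.4, 1, 0)
  inc <- make_incidence_schedule(seed = 1, ages = ages, base_rate = 0.2,
                                 noise_sd = 0, shape_fun = shape6)
  mort <- make_mortality_schedule(seed = 1, ages = ages, level = 0)
  mk <- function(h) model_config(
    cohort = cohort_spec(0.5, 1000, 2000, "t"), horizon_years = h,
    incidence = inc, mortality = mort)
  spec <- intervention_spec("1a")
  for (arm in list(NULL, spec)) {
    t6 <- run_cohort(mk(6), arm)$totals
    t12 <- run_cohort(mk(12), arm)$totals
    expect_equal(t12[["disc_cost_total"]], t6[["disc_cost_total"]],
                 tolerance = 1e-12)
    expect_equal(t12[["disc_decayed_teeth"]], t6[["disc_decayed_teeth"]],
                 tolerance = 1e-12)
    expect_equal(t12[["disc_qalys"]], t6[["disc_qalys"]],
                 tolerance = 1e-12)
  }
})

test_that("discounted streams never exceed undiscounted ones", {
  for (id in c("1a", "2a", "3")) {
    cfg <- fixture_config(id)
    tot <- run_cohort(cfg, intervention_spec(id))$totals
    for (col in c("cases", "decayed_teeth", "dalys", "qalys",
                  "cost_intervention", "cost_healthcare", "cost_total")) {
      expect_lte(tot[[paste0("disc_", col)]], tot[[col]])
    }
  }
})

test_that("interventions outside the cohort's reachable dentition are rejected", {
  ages <- 0:30
  cfg <- model_config(
    cohort = cohort_spec(20, 100, 200, "adults"), horizon_years = 2,
    incidence = make_incidence_schedule(seed = 1, ages = ages),
    mortality = make_mortality_schedule(seed = 1, ages = ages))
  expect_error(run_cohort(cfg, intervention_spec("1a")), "deciduous")
})

test_that("cycle traces export as tidy CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- run_cohort(small_config())
  write_trace_csv(tr, path)
  long <- read.csv(path)
  expect_setequal(unique(long$state),
                  c("caries_free", "caries", "edentulous", "dead"))
  expect_equal(nrow(long), 4 * nrow(tr$trace))
})
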