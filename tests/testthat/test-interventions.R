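test_that("preventive fraction transform is exact", {
  expect_equal(apply_preventive_fraction(0.2, 0), 0.2)
  expect_equal(apply_preventive_fraction(0.2, 1), 0)
  expect_equal(apply_preventive_fraction(0.2, 0.37), 0.126)
  # consistent with the definition pf = 1 - rate_I / rate_C
  for (pf in c(0.1, 0.37, 0.43, 0.9)) {
    expect_equal(1 - apply_preventive_fraction(0.3, pf) / 0.3, pf)
  }
  # adjusted incidence strictly inside (0, baseline) for pf in (0, 1)
  for (pf in seq(0.05, 0.95, by = 0.15)) {
    adj <- apply_preventive_fraction(0.25, pf)
    expect_true(adj > 0 && adj < 0.25)
  }
  expect_error(apply_preventive_fraction(0.2, 1.2), "pf")
})

test_that("odds-ratio risk transform is exact", {
  # null odds ratio leaves every baseline risk unchanged
  for (p0 in seq(0, 0.95, by = 0.13)) {
    expect_equal(odds_ratio_to_adjusted_risk(p0, 1), p0)
  }
  expect_equal(odds_ratio_to_adjusted_risk(0, 0.12), 0)
  # hand evaluation: 0.12 * 0.1 / (0.9 + 0.012) = 0.0131578...
  expect_equal(odds_ratio_to_adjusted_risk(0.10, 0.12), 0.012 / 0.912)
  expect_equal(odds_ratio_to_adjusted_risk(0.10, 0.12), 0.013158,
               tolerance = 1e-4)
  # protective odds ratios reduce risk everywhere in (0, 1)
  for (p0 in seq(0.05, 0.95, by = 0.1)) {
    expect_lt(odds_ratio_to_adjusted_risk(p0, 0.12), p0)
  }
  expect_error(odds_ratio_to_adjusted_risk(1, 0.12), "p0")
})

test_that("dmft differences convert to per-cycle case reductions", {
  expect_equal(anticipatory_guidance_case_reduction(0, 1.64, 6), 0)
  expect_equal(anticipatory_guidance_case_reduction(-0.15, 1.64, 6),
               0.15 / 1.64 / 6)
  expect_equal(anticipatory_guidance_case_reduction(-0.15, 1.64, 6),
               0.01524, tolerance = 1e-3)
  expect_equal(anticipatory_guidance_case_reduction(-0.18, 1.64, 6),
               0.01829, tolerance = 1e-3)
  expect_error(anticipatory_guidance_case_reduction(0.1, 1.64, 6),
               "delta_dmft")
})

test_that("program cost schedules reproduce the fee arithmetic", {
  costs <- cost_params()
  # sealants: screening + four molars in one visit, first year only
  c3 <- fixture_cohort_of("3")
  expect_equal(intervention_cost_for_year(intervention_spec("3"), costs,
                                          c3, 0),
               94025 * (29.25 + 4 * 49.00))
  expect_equal(intervention_cost_for_year(intervention_spec("3"), costs,
                                          c3, 1), 0)
  # non-dental varnish: two applications/year at the step-down rate
  c2 <- fixture_cohort_of("2b")
  for (yr in 0:1) {
    expect_equal(intervention_cost_for_year(intervention_spec("2b"), costs,
                                            c2, yr),
                 333651 * 2 * 36.80 * 0.769)
  }
  expect_equal(intervention_cost_for_year(intervention_spec("2b"), costs,
                                          c2, 2), 0)
  # home visits: 1 visit in year one then 2/year
  c1 <- fixture_cohort_of("1a")
  expect_equal(intervention_cost_for_year(intervention_spec("1a"), costs,
                                          c1, 0),
               45677 * (23.33 + 12.34))
  # telehealth: total over the window is 11 visits at the telehealth fee
  total_1b <- sum(vapply(0:5, function(yr) {
    intervention_cost_for_year(intervention_spec("1b"), costs, c1, yr)
  }, numeric(1)))
  expect_equal(total_1b, 11 * 16.04 * 45677)
})

test_that("the published 2a first-year cost is exposed alongside the formula", {
  spec <- intervention_spec("2a")
  formula_cost <- intervention_cost_for_year(spec, cost_params(),
                                             fixture_cohort_of("2a"), 0)
  expect_equal(formula_cost, 333651 * (29.25 + 2 * 36.80))
  expect_equal(round(formula_cost / 1e5) / 10, 34.3)
  expect_equal(spec$printed_first_year_cost_m, 34.6)
})

test_that("screening costs are restricted to the programs that screen", {
  expect_true(intervention_spec("2a")$includes_screening_first_visit)
  expect_true(intervention_spec("3")$includes_screening_first_visit)
  expect_false(intervention_spec("2b")$includes_screening_first_visit)
  bad <- intervention_spec("1b")
  bad$includes_screening_first_visit <- TRUE
  expect_error(cariescea:::validate_intervention_spec(bad), "screening")
})

test_that("both varnish delivery modes share one effectiveness stream", {
  cfg <- fixture_config("2a")
  t2a <- run_cohort(cfg, intervention_spec("2a"))
  t2b <- run_cohort(cfg, intervention_spec("2b"))
  for (col in c("cases", "decayed_teeth", "dalys", "qalys",
                "disc_decayed_teeth", "disc_dalys", "disc_qalys",
                "cost_healthcare")) {
    expect_identical(t2a$totals[[col]], t2b$totals[[col]])
  }
  expect_lt(t2b$totals[["cost_intervention"]],
            t2a$totals[["cost_intervention"]])
})
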