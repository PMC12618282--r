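test_that("incidence generation is deterministic and respects edge cases", {
  a <- make_incidence_schedule(seed = 1, base_rate = 0.15,
                               low_income_ratio = 1.5, noise_sd = 0.1)
  b <- make_incidence_schedule(seed = 1, base_rate = 0.15,
                               low_income_ratio = 1.5, noise_sd = 0.1)
  expect_identical(a, b)
  expect_false(identical(
    a, make_incidence_schedule(seed = 2, base_rate = 0.15,
                               low_income_ratio = 1.5, noise_sd = 0.1)))

  expect_warning(zero <- make_incidence_schedule(seed = 1, base_rate = 0),
                 "degenerate")
  expect_true(all(zero$rate_general == 0))
  expect_true(all(zero$rate_low_income == 0))

  same <- make_incidence_schedule(seed = 1, low_income_ratio = 1)
  expect_identical(same$rate_low_income, same$rate_general)
})

test_that("generated schedules are valid probabilities for any admissible input", {
  for (k in 1:25) {
    p <- withr::with_seed(k, list(base = runif(1), ratio = 1 + rexp(1),
                                  noise = runif(1, 0, 0.5),
                                  level = runif(1)))
    inc <- suppressWarnings(
      make_incidence_schedule(seed = k, base_rate = p$base,
                              low_income_ratio = p$ratio,
                              noise_sd = p$noise))
    expect_true(all(inc$rate_general >= 0 & inc$rate_general <= 1))
    expect_true(all(inc$rate_low_income >= 0 & inc$rate_low_income <= 1))
    expect_true(all(inc$deciduous_share >= 0 & inc$deciduous_share <= 1))
    mort <- make_mortality_schedule(seed = k, level = p$level)
    for (col in c("male", "female", "combined")) {
      expect_true(all(mort[[col]] >= 0 & mort[[col]] <= 1))
    }
  }
})

test_that("raising the low-income ratio never lowers a low-income rate", {
  for (k in 1:10) {
    lo <- make_incidence_schedule(seed = k, low_income_ratio = 1.2)
    hi <- make_incidence_schedule(seed = k, low_income_ratio = 2.5)
    expect_true(all(hi$rate_low_income >= lo$rate_low_income))
  }
})

test_that("mixed-dentition split follows the eruption profile and sums to the total", {
  sched <- make_incidence_schedule(seed = 1, noise_sd = 0)
  total_at <- function(age) {
    unname(sum(split_mixed_dentition(sched, age)))
  }
  # pre-eruption: everything deciduous
  s3 <- split_mixed_dentition(sched, 3)
  expect_equal(s3[["permanent"]], 0)
  expect_equal(s3[["deciduous"]], total_at(3))
  # end of the mixed-dentition window: everything permanent
  s14 <- split_mixed_dentition(sched, 14)
  expect_equal(s14[["deciduous"]], 0)
  # midpoint of the linear profile (age 9.5): even split
  s95 <- split_mixed_dentition(sched, 9.5)
  expect_equal(s95[["deciduous"]], s95[["permanent"]], tolerance = 1e-12)
  expect_equal(sum(s95), total_at(9.5))
  expect_equal(deciduous_share_profile(9.5), 0.5)
  # components always sum to the interpolated total
  for (age in seq(0.5, 20, by = 1.7)) {
    expect_equal(sum(split_mixed_dentition(sched, age)), total_at(age),
                 tolerance = 1e-12)
  }
  expect_error(split_mixed_dentition(sched, 99), "age")
})

test_that("mortality generation is deterministic with saturating extremes", {
  a <- make_mortality_schedule(seed = 7, level = 3e-4)
  expect_identical(a, make_mortality_schedule(seed = 7, level = 3e-4))
  expect_true(all(make_mortality_schedule(seed = 1, level = 0)$combined == 0))
  expect_true(all(make_mortality_schedule(seed = 1, level = 1)$combined == 1))
  # males carry the higher hazard at every age
  expect_true(all(a$male >= a$female))
})

test_that("schedule CSV round trips preserve the rates", {
  inc <- make_incidence_schedule(seed = 3)
  mort <- make_mortality_schedule(seed = 3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_incidence_csv(inc, f1)
  write_mortality_csv(mort, f2)
  inc2 <- read_incidence_csv(f1)
  mort2 <- read_mortality_csv(f2)
  expect_equal(as.data.frame(inc2), as.data.frame(inc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(inc2, "occlusal_molar_share"),
               attr(inc, "occlusal_molar_share"))
  expect_equal(mort2$combined, mort$combined, tolerance = 1e-12)
})
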