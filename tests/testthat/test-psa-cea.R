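test_that("zero-sd draws are the parameter means and collapse the PSA", {
  cfg <- zero_sd_config(fixture_config("3"))
  spec <- zero_sd_spec(intervention_spec("3"))
  d1 <- sample_parameters(cfg, spec, seed = 1, iteration = 1)
  d2 <- sample_parameters(cfg, spec, seed = 99, iteration = 7)
  expect_identical(d1, d2)
  expect_equal(d1$disability_weight, 0.010)
  expect_equal(d1$utility_gain, 0.05)
  expect_equal(d1$teeth_per_case, 1.64)
  expect_equal(d1$effect$odds_ratio, 0.12)

  res <- run_psa(cfg, spec, n_iter = 3, seed = 1)
  det <- incremental_outcomes(run_cohort(cfg),
                              run_cohort(cfg, spec))$discounted
  expect_equal(unname(res$summary$means), unname(det))
  expect_equal(unname(res$summary$ses), rep(0, 4))
})

test_that("draws and full PSA results are seed-reproducible", {
  cfg <- fixture_config("3")
  spec <- intervention_spec("3")
  expect_identical(sample_parameters(cfg, spec, seed = 4, iteration = 11),
                   sample_parameters(cfg, spec, seed = 4, iteration = 11))
  expect_false(identical(
    sample_parameters(cfg, spec, seed = 4, iteration = 11),
    sample_parameters(cfg, spec, seed = 4, iteration = 12)))
  r1 <- run_psa(cfg, spec, n_iter = 20, seed = 1)
  r2 <- run_psa(cfg, spec, n_iter = 20, seed = 1)
  expect_identical(r1, r2)
  expect_false(identical(r1$iterations,
                         run_psa(cfg, spec, n_iter = 20,
                                 seed = 2)$iterations))
})

test_that("draws respect their truncation bounds and means", {
  cfg <- fixture_config("1a")
  spec <- intervention_spec("1a")
  draws <- vapply(1:2000, function(i) {
    d <- sample_parameters(cfg, spec, seed = 42, iteration = i)
    c(d$disability_weight, d$baseline_utility, d$teeth_per_case,
      d$effect$delta_dmft)
  }, numeric(4))
  expect_true(all(draws[1, ] >= 0))
  expect_true(all(draws[2, ] <= 1))
  expect_true(all(draws[3, ] >= 0))
  expect_true(all(draws[4, ] <= 0))
  # closed-form truncated-normal mean as the oracle for the disability
  # weight (lower truncation at 0, alpha = -mu/sd = -2.5)
  alpha <- (0 - 0.010) / 0.004
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  mu_trunc <- 0.010 + 0.004 * lambda
  sd_trunc <- 0.004 * sqrt(1 + alpha * lambda - lambda^2)
  se <- sd_trunc / sqrt(ncol(draws))
  expect_lt(abs(mean(draws[1, ]) - mu_trunc), 3 * se)
})

test_that("ICER handles ratios, dominance and undefined effects", {
  r <- icer(57.5e6, 65198)
  expect_equal(r$status, "ratio")
  expect_equal(round(r$value), 882)
  expect_equal(icer(-25.0e6, 94)$status, "dominant")
  expect_equal(icer(10, -5)$status, "dominated")
  expect_equal(icer(0, 10)$value, 0)     # free effect
  und <- icer(5, 0)
  expect_equal(und$status, "undefined")
  expect_true(is.na(und$value))
  expect_equal(format(icer(-1, 2)), "dominant")
})

test_that("a null intervention yields zero deltas and undefined ICERs", {
  cfg <- zero_sd_config(fixture_config("2b"))
  res <- run_psa(cfg, null_intervention(), n_iter = 2, seed = 1)
  expect_equal(unname(res$summary$means), rep(0, 4))
  expect_equal(res$summary$icer_per_dt$status, "undefined")
  tab <- summarize_cea(list(null = res))
  expect_equal(tab$delta_cost, 0)
  expect_equal(tab$icer_per_qaly_status, "undefined")
})

test_that("the summary ICER is the ratio of per-iteration means", {
  cfg <- fixture_config("3")
  res <- run_psa(cfg, intervention_spec("3"), n_iter = 25, seed = 5)
  it <- res$iterations
  expect_equal(res$summary$icer_per_dt$value,
               mean(it$delta_cost) / mean(it$delta_dt))
  expect_equal(res$summary$icer_per_qaly$value,
               mean(it$delta_cost) / mean(it$delta_qaly))
})

test_that("cost-effectiveness probability is monotone in willingness to pay", {
  cfg <- fixture_config("3")
  res <- run_psa(cfg, intervention_spec("3"), n_iter = 40, seed = 2)
  wtps <- c(1e3, 1e5, 1e6, 1e7, 1e8, 1e10)
  probs <- vapply(wtps, function(w) ce_probability(res, w, "qaly"),
                  numeric(1))
  expect_true(all(diff(probs) >= 0))
  # limits: effects here are all positive, costs all positive
  expect_true(all(res$iterations$delta_qaly > 0))
  expect_equal(probs[length(probs)], 1)
  expect_equal(ce_probability(res, 1e-6, "qaly"), 0)
})

test_that("scaling all costs scales ICERs and leaves effects untouched", {
  cfg <- fixture_config("3")
  res <- run_psa(cfg, intervention_spec("3"), n_iter = 15, seed = 3)
  k <- 2.5
  scaled <- res
  for (col in c("delta_cost", "undisc_delta_cost")) {
    scaled$iterations[[col]] <- k * scaled$iterations[[col]]
  }
  t0 <- summarize_cea(list(x = res))
  t1 <- summarize_cea(list(x = scaled))
  expect_equal(t1$icer_per_dt, k * t0$icer_per_dt)
  expect_equal(t1$icer_per_daly, k * t0$icer_per_daly)
  expect_equal(t1$icer_per_qaly, k * t0$icer_per_qaly)
  expect_equal(t1$delta_dt, t0$delta_dt)
  expect_equal(t1$delta_qaly, t0$delta_qaly)
})

test_that("league tables rank cheaper equal-effect programs first", {
  cfg <- zero_sd_config(fixture_config("2a"))
  res_a <- run_psa(cfg, zero_sd_spec(intervention_spec("2a")),
                   n_iter = 2, seed = 1)
  res_b <- run_psa(cfg, zero_sd_spec(intervention_spec("2b")),
                   n_iter = 2, seed = 1)
  tab <- summarize_cea(list(`2a` = res_a, `2b` = res_b))
  expect_equal(tab$intervention, c("2b", "2a"))
  expect_equal(tab$delta_dt[1], tab$delta_dt[2])
  expect_lt(tab$delta_cost[1], tab$delta_cost[2])
})
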