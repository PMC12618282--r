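# Probabilistic sensitivity analysis and cost-effectiveness summaries:
# Monte Carlo propagation of parameter distributions through the cohort
# model, incremental outcomes versus the no-intervention comparator,
# ICERs with dominance handling, and cost-effectiveness probabilities via
# net monetary benefit at the willingness-to-pay thresholds.

# Truncated-normal sampling by resampling; sd = 0 degenerates to the mean.
rtnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:10000) {
    x <- rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncated-normal resampling failed to find a value in range",
       call. = FALSE)
}

iteration_seed <- function(seed, iteration) {
  as.integer((as.double(seed) %% 65011 * 1009 + iteration * 7919) %%
               2147483647)
}

#' Draw one set of uncertain parameters
#'
#' Samples every uncertain model parameter for one PSA iteration: the
#' intervention effect size (normal around the published estimate), the
#' disability weight (normal 0.010, SD 0.004, truncated at 0), the baseline
#' caries utility (normal 0.9, SD 0.120, truncated at 1, from which the
#' halved utility gain is derived), decayed teeth per case (truncated
#' normal at 0), and the fees with published SDs (check-up, restoration,
#' home-visit travel; truncated at 0).  Truncation is by resampling.  The
#' draw is fully determined by `(seed, iteration)`.
#'
#' @param config A [model_config()].
#' @param intervention An [intervention_spec()] (its effect family decides
#'   which effect parameters are drawn), or `NULL` for none.
#' @param seed PSA-level seed.
#' @param iteration Iteration index, `>= 1`.
#' @return A `parameter_draw` list consumable by [run_cohort()].
#' @export
sample_parameters <- function(config, intervention = NULL,
                              seed = config$econ$rng_seed, iteration = 1L) {
  chk(is_number(iteration) && iteration >= 1, "iteration", "must be >= 1")
  v <- config$valuation
  costs <- config$costs
  withr::with_seed(iteration_seed(seed, iteration), {
    effect <- if (is.null(intervention)) NULL else {
      eff <- intervention$effect
      switch(intervention$effect_kind,
        ABS_DMFT_REDUCTION = list(
          delta_dmft = rtnorm1(eff$delta_dmft, eff$sd, upper = 0)),
        PREVENTIVE_FRACTION = list(
          pf_deciduous = rtnorm1(eff$pf_deciduous, eff$sd_deciduous, 0, 1),
          pf_permanent = rtnorm1(eff$pf_permanent, eff$sd_permanent, 0, 1)),
        ODDS_RATIO = list(
          odds_ratio = rtnorm1(eff$odds_ratio, eff$sd, lower = 1e-9)))
    }
    dw <- rtnorm1(v$disability_weight$mean, v$disability_weight$sd,
                  lower = 0)
    util <- rtnorm1(v$baseline_utility$mean, v$baseline_utility$sd,
                    upper = 1)
    structure(
      list(effect = effect,
           disability_weight = dw,
           baseline_utility = util,
           utility_gain = (1 - util) / 2,
           teeth_per_case = rtnorm1(v$teeth_per_case$mean,
                                    v$teeth_per_case$sd, lower = 0),
           checkup_fee = rtnorm1(costs$checkup_fee$mean,
                                 costs$checkup_fee$sd, lower = 0),
           restoration_fee = rtnorm1(costs$restoration_fee_per_tooth$mean,
                                     costs$restoration_fee_per_tooth$sd,
                                     lower = 0),
           travel_cost = rtnorm1(costs$home_visit_travel$mean,
                                 costs$home_visit_travel$sd, lower = 0)),
      class = "parameter_draw")
  })
}

#' Run the probabilistic sensitivity analysis for one intervention
#'
#' For each Monte Carlo iteration, draws one parameter set, runs the
#' comparator and the intervention arm on that shared draw (common random
#' numbers, so the incremental outcome reflects the parameter uncertainty
#' rather than independent sampling noise), and records the discounted and
#' undiscounted incremental cost, decayed teeth prevented, DALYs averted
#' and QALYs gained.  Attaches summary statistics: means, standard errors
#' (`sd / sqrt(n)`), ratio-of-means ICERs and cost-effectiveness
#' probabilities at the configured willingness-to-pay thresholds.
#'
#' @param config A [model_config()].
#' @param intervention An [intervention_spec()].
#' @param n_iter Number of iterations (default from the config).
#' @param seed RNG seed (default from the config).
#' @param recovery Passed to [run_cohort()].
#' @return A `psa_result`.
#' @export
#' @examples
#' \donttest{
#' res <- run_psa(fixture_config("3"), intervention_spec("3"), n_iter = 50)
#' res$summary$ce_qaly
#' }
run_psa <- function(config, intervention,
                    n_iter = config$econ$n_psa_iterations,
                    seed = config$econ$rng_seed,
                    recovery = "one_cycle") {
  chk(is_number(n_iter) && n_iter >= 1, "n_iter", "must be >= 1")
  validate_model_config(config)
  validate_intervention_spec(intervention)

  cols <- c("delta_cost", "delta_dt", "delta_daly", "delta_qaly")
  disc <- matrix(NA_real_, nrow = n_iter, ncol = 4L,
                 dimnames = list(NULL, cols))
  undisc <- disc
  n_clipped <- 0L
  for (i in seq_len(n_iter)) {
    draw <- sample_parameters(config, intervention, seed, i)
    comp <- run_cohort(config, NULL, draw = draw, recovery = recovery)
    # collect per-cycle incidence-clipping warnings into one summary note
    arm <- withCallingHandlers(
      run_cohort(config, intervention, draw = draw, recovery = recovery),
      warning = function(w) {
        if (grepl("clipping to zero incidence", conditionMessage(w))) {
          n_clipped <<- n_clipped + 1L
          invokeRestart("muffleWarning")
        }
      })
    inc <- incremental_outcomes(comp, arm)
    disc[i, ] <- inc$discounted
    undisc[i, ] <- inc$undiscounted
  }
  if (n_clipped > 0L) {
    message(sprintf(
      "note: dmft-derived reduction clipped adjusted incidence to zero in %d cycle evaluations",
      n_clipped))
  }
  iterations <- data.frame(iteration = seq_len(n_iter), disc,
                           setNames(as.data.frame(undisc),
                                    paste0("undisc_", cols)))

  means <- colMeans(disc)
  ses <- apply(disc, 2L, sd) / sqrt(n_iter)
  result <- structure(
    list(iterations = iterations,
         summary = list(
           n = n_iter, means = means, ses = ses,
           icer_per_dt = icer(means[["delta_cost"]], means[["delta_dt"]]),
           icer_per_daly = icer(means[["delta_cost"]],
                                means[["delta_daly"]]),
           icer_per_qaly = icer(means[["delta_cost"]],
                                means[["delta_qaly"]])),
         meta = list(intervention = intervention$id,
                     label = intervention$label,
                     scenario = config$scenario,
                     n_iter = n_iter, seed = seed,
                     wtp_per_daly = config$econ$wtp_per_daly,
                     wtp_per_qaly = config$econ$wtp_per_qaly)),
    class = "psa_result")
  result$summary$ce_daly <- ce_probability(result,
                                           config$econ$wtp_per_daly,
                                           "daly")
  result$summary$ce_qaly <- ce_probability(result,
                                           config$econ$wtp_per_qaly,
                                           "qaly")
  result
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<psa_result> %s (%s), %d iterations\n",
              x$meta$label, x$meta$intervention, s$n))
  cat(sprintf("  dCost AUD %.1fM (SE %.2fM) | dDT %.0f (SE %.0f) | dDALY %.2f | dQALY %.2f\n",
              s$means[["delta_cost"]] / 1e6, s$ses[["delta_cost"]] / 1e6,
              s$means[["delta_dt"]], s$ses[["delta_dt"]],
              s$means[["delta_daly"]], s$means[["delta_qaly"]]))
  cat(sprintf("  ICER: %s/DT, %s/DALY, %s/QALY | CE: %.1f%% (DALY), %.1f%% (QALY)\n",
              format(x$summary$icer_per_dt),
              format(x$summary$icer_per_daly),
              format(x$summary$icer_per_qaly),
              100 * s$ce_daly, 100 * s$ce_qaly))
  invisible(x)
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' `delta_cost / delta_effect` when the effect difference buys something:
#' an intervention that is cheaper and more effective is `"dominant"`, one
#' that is costlier and less effective is `"dominated"`, and a zero effect
#' difference with a nonzero cost difference yields an explicit
#' `"undefined"` marker rather than an error.
#'
#' @param delta_cost Incremental cost (AUD).
#' @param delta_effect Incremental effect (DT, DALYs or QALYs).
#' @return An `icer` object: `list(value, status)` with status one of
#'   `"ratio"`, `"dominant"`, `"dominated"`, `"undefined"`.
#' @export
#' @examples
#' icer(57.5e6, 65198)   # 882 AUD per unit
#' icer(-25e6, 94)       # dominant
icer <- function(delta_cost, delta_effect) {
  status <- if (delta_effect == 0) {
    "undefined"
  } else if (delta_cost < 0 && delta_effect > 0) {
    "dominant"
  } else if (delta_cost > 0 && delta_effect < 0) {
    "dominated"
  } else {
    "ratio"
  }
  value <- if (status == "ratio") delta_cost / delta_effect else NA_real_
  structure(list(value = value, status = status), class = "icer")
}

#' @export
format.icer <- function(x, ...) {
  switch(x$status,
         ratio = formatC(x$value, format = "f", digits = 0,
                         big.mark = ","),
         dominant = "dominant",
         dominated = "dominated",
         undefined = "undefined")
}

#' @export
print.icer <- function(x, ...) {
  cat("<icer>", format(x), "\n")
  invisible(x)
}

#' Probability an intervention is cost-effective
#'
#' Share of PSA iterations with positive net monetary benefit
#' `wtp * delta_effect - delta_cost > 0` at the given willingness-to-pay
#' threshold.
#'
#' @param result A `psa_result`.
#' @param wtp Willingness to pay per effect unit, `> 0`.
#' @param effect `"daly"` or `"qaly"`.
#' @return Proportion in `[0, 1]`.
#' @export
ce_probability <- function(result, wtp, effect = c("daly", "qaly")) {
  effect <- match.arg(effect)
  chk(is_number(wtp) && wtp > 0, "wtp", "must be > 0")
  it <- result$iterations
  eff <- if (effect == "daly") it$delta_daly else it$delta_qaly
  mean(wtp * eff - it$delta_cost > 0)
}

icer_rank_key <- function(x) {
  switch(x$status, dominant = -Inf, dominated = Inf, undefined = Inf,
         ratio = x$value)
}

#' Cost-effectiveness league table
#'
#' One row per intervention with mean (SE) incremental cost, decayed teeth
#' prevented, DALYs averted and QALYs gained, the three ratio-of-means
#' ICERs, and the cost-effectiveness probabilities at both thresholds.
#' Rows are ranked by cost per decayed tooth prevented, ascending, with
#' dominant interventions first.
#'
#' @param results A (named) list of `psa_result` objects.
#' @param undiscounted Report the undiscounted incremental streams instead.
#' @return A `cea_table` data frame.
#' @export
summarize_cea <- function(results, undiscounted = FALSE) {
  chk(length(results) >= 1, "results", "need at least one psa_result")
  rows <- lapply(results, function(res) {
    it <- res$iterations
    pick <- function(col) if (undiscounted) it[[paste0("undisc_", col)]]
                          else it[[col]]
    n <- nrow(it)
    m <- vapply(c("delta_cost", "delta_dt", "delta_daly", "delta_qaly"),
                function(col) mean(pick(col)), numeric(1))
    se <- vapply(c("delta_cost", "delta_dt", "delta_daly", "delta_qaly"),
                 function(col) sd(pick(col)) / sqrt(n), numeric(1))
    i_dt <- icer(m[["delta_cost"]], m[["delta_dt"]])
    i_daly <- icer(m[["delta_cost"]], m[["delta_daly"]])
    i_qaly <- icer(m[["delta_cost"]], m[["delta_qaly"]])
    data.frame(
      intervention = res$meta$intervention, label = res$meta$label,
      delta_cost = m[["delta_cost"]], delta_cost_se = se[["delta_cost"]],
      delta_dt = m[["delta_dt"]], delta_dt_se = se[["delta_dt"]],
      delta_daly = m[["delta_daly"]], delta_daly_se = se[["delta_daly"]],
      delta_qaly = m[["delta_qaly"]], delta_qaly_se = se[["delta_qaly"]],
      icer_per_dt = i_dt$value, icer_per_dt_status = i_dt$status,
      icer_per_daly = i_daly$value, icer_per_daly_status = i_daly$status,
      icer_per_qaly = i_qaly$value, icer_per_qaly_status = i_qaly$status,
      ce_daly = ce_probability(res, res$meta$wtp_per_daly, "daly"),
      ce_qaly = ce_probability(res, res$meta$wtp_per_qaly, "qaly"),
      rank_key = icer_rank_key(i_dt),
      row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rank_key, out$delta_cost), ]
  out$rank_key <- NULL
  rownames(out) <- NULL
  structure(out, class = c("cea_table", "data.frame"))
}

#' @export
print.cea_table <- function(x, ...) {
  fmt_m <- function(v) sprintf("%.1fM", v / 1e6)
  cat("Cost-effectiveness league table (ranked by AUD per DT prevented)\n")
  df <- data.frame(
    intervention = x$intervention,
    `dCost` = fmt_m(x$delta_cost),
    `dDT` = sprintf("%.0f", x$delta_dt),
    `dDALY` = sprintf("%.1f", x$delta_daly),
    `dQALY` = sprintf("%.1f", x$delta_qaly),
    `AUD/DT` = ifelse(x$icer_per_dt_status == "ratio",
                      sprintf("%.0f", x$icer_per_dt),
                      x$icer_per_dt_status),
    `AUD/DALY` = ifelse(x$icer_per_daly_status == "ratio",
                        sprintf("%.3g", x$icer_per_daly),
                        x$icer_per_daly_status),
    `AUD/QALY` = ifelse(x$icer_per_qaly_status == "ratio",
                        sprintf("%.3g", x$icer_per_qaly),
                        x$icer_per_qaly_status),
    `CE(DALY)` = sprintf("%.1f%%", 100 * x$ce_daly),
    `CE(QALY)` = sprintf("%.1f%%", 100 * x$ce_qaly),
    check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
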