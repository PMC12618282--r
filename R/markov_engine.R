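# Closed-cohort four-state Markov engine with one-year cycles.
# States: caries-free, dental caries, edentulous (complete tooth loss) and
# dead.  Dead is absorbing; edentulism has zero inflow at all modelled ages
# (it only accrues from age 20+) and is retained for structural fidelity.
# The cohort is propagated as deterministic expected values (fractional
# persons); parameter uncertainty is handled by the PSA layer.

health_states <- c("caries_free", "caries", "edentulous", "dead")

#' Discount a value to present terms
#'
#' `amount / (1 + rate)^cycle_index`; cycle 0 is undiscounted.
#'
#' @param amount Value (vectorised).
#' @param cycle_index Cycle number, 0-based (vectorised).
#' @param rate Annual discount rate, `>= 0`.
#' @return Discounted value.
#' @export
#' @examples
#' discount(100, 2, 0.03)  # 94.2596
discount <- function(amount, cycle_index, rate) {
  chk(all(cycle_index >= 0), "cycle_index", "must be >= 0")
  chk(is_number(rate) && rate >= 0, "rate", "must be >= 0")
  amount / (1 + rate)^cycle_index
}

#' One Markov cycle transition
#'
#' Advances a state-occupancy vector through one cycle.  Deaths apply to
#' every alive state at the background mortality probability; incident
#' caries arises among surviving caries-free members at the summed
#' deciduous + permanent probability.  Under the default one-cycle recovery
#' policy an incident case occupies the caries state for one cycle (the
#' episode is treated or arrests) and then returns to caries-free; under
#' `"until_treated"` the caries state is left only by death.  Mass is
#' conserved exactly and the dead state never decreases.
#'
#' @param occupancy Named or ordered numeric of length 4
#'   (`caries_free, caries, edentulous, dead`), nonnegative.
#' @param incidence_deciduous,incidence_permanent Per-person annual
#'   probabilities of a new case in each dentition; their sum must be a
#'   probability.
#' @param mortality Annual death probability.
#' @param recovery `"one_cycle"` (default) or `"until_treated"`.
#' @return `list(occupancy, cases_deciduous, cases_permanent)` where the
#'   case counts are the incident events during the cycle.
#' @export
transition_step <- function(occupancy, incidence_deciduous,
                            incidence_permanent, mortality,
                            recovery = c("one_cycle", "until_treated")) {
  recovery <- match.arg(recovery)
  chk(length(occupancy) == 4L && all(is.finite(occupancy)),
      "occupancy", "must be 4 finite state counts")
  if (any(occupancy < -1e-9)) {
    stop("internal consistency error: negative state occupancy",
         call. = FALSE)
  }
  i_total <- incidence_deciduous + incidence_permanent
  chk(incidence_deciduous >= 0 && incidence_permanent >= 0 && i_total <= 1,
      "incidence", "dentition rates must be nonnegative and sum to <= 1")
  chk(is_prob(mortality), "mortality", "must be a probability")

  cf <- occupancy[[1L]]; ca <- occupancy[[2L]]
  ed <- occupancy[[3L]]; de <- occupancy[[4L]]
  deaths <- mortality * (cf + ca + ed)
  cases <- cf * (1 - mortality) * i_total
  recovered <- if (recovery == "one_cycle") ca * (1 - mortality) else 0
  carried <- if (recovery == "one_cycle") 0 else ca * (1 - mortality)

  nxt <- c(caries_free = cf * (1 - mortality) * (1 - i_total) + recovered,
           caries = cases + carried,
           edentulous = ed * (1 - mortality),
           dead = de + deaths)
  frac_dec <- if (i_total > 0) incidence_deciduous / i_total else 0
  list(occupancy = nxt,
       cases_deciduous = cases * frac_dec,
       cases_permanent = cases * (1 - frac_dec))
}

check_intervention_reachable <- function(spec, config) {
  if (is.null(spec)) return(invisible(NULL))
  lo <- min(config$cohort$start_ages)
  hi <- max(config$cohort$start_ages) + config$horizon_years
  ok <- switch(spec$target,
    deciduous = lo < 14,          # some deciduous incidence on the track
    both_dentitions = TRUE,
    occlusal_molars = hi > 5,     # some permanent incidence on the track
    TRUE)
  chk(ok, "intervention",
      sprintf("intervention %s targets %s but the cohort ages [%g, %g] never have it",
              spec$id, spec$target, lo, hi))
  invisible(NULL)
}

#' Run the closed-cohort model for one arm
#'
#' Propagates the cohort (each single-age sub-cohort, the low-income
#' population split evenly across start ages) through `horizon_years`
#' one-year cycles, applying the intervention's effect transform to the
#' dentition-specific incidence at every cycle and accruing intervention
#' costs over the program's cost window.  Incident-event accumulators
#' (cases, decayed teeth, episode DALYs/QALYs, per-case healthcare costs)
#' count events directly; state occupancy is additionally reported as
#' half-cycle-corrected person-years (trapezoid average of start- and
#' end-of-cycle occupancy) when `cycle_correction = "half_cycle"`.
#' Costs and outcomes are discounted per [discount()].
#'
#' @param config A validated [model_config()].
#' @param intervention An [intervention_spec()], or `NULL` for the
#'   no-intervention comparator.
#' @param draw Optional PSA parameter draw from [sample_parameters()];
#'   `NULL` runs at the parameter means.
#' @param recovery Caries-state dwell policy, see [transition_step()].
#' @param cycle_correction `"half_cycle"` (default) or `"none"`, affecting
#'   the reported occupancy person-years only.
#' @return A `cycle_trace`: list with `trace` (one row per sub-cohort and
#'   cycle) and `totals` (named vector of cumulative outcomes, discounted
#'   and undiscounted).
#' @export
#' @examples
#' cfg <- fixture_config("3")
#' tr <- run_cohort(cfg, intervention_spec("3"))
#' tr$totals[["disc_decayed_teeth"]]
run_cohort <- function(config, intervention = NULL, draw = NULL,
                       recovery = c("one_cycle", "until_treated"),
                       cycle_correction = c("half_cycle", "none")) {
  recovery <- match.arg(recovery)
  cycle_correction <- match.arg(cycle_correction)
  check_intervention_reachable(intervention, config)

  H <- config$horizon_years
  rate <- config$econ$discount_rate_per_year
  v <- config$valuation
  costs <- config$costs

  dw <- draw$disability_weight %||% v$disability_weight$mean
  ug <- draw$utility_gain %||% v$utility_gain
  tpc <- draw$teeth_per_case %||% v$teeth_per_case$mean
  sf <- v$symptomatic_fraction$default
  per_yld <- yld_per_case(v, disability_weight = dw)
  per_qaly <- qaly_gain_per_case(v, utility_gain = ug)
  per_treat <- treatment_cost_per_case(costs, v,
                                       checkup_fee = draw$checkup_fee,
                                       restoration_fee = draw$restoration_fee,
                                       teeth_per_case = tpc)
  occl <- attr(config$incidence, "occlusal_molar_share")
  disc_f <- (1 + rate)^-(0:(H - 1))

  starts <- config$cohort$start_ages
  subsize <- config$cohort$size_low_income / length(starts)
  blocks <- vector("list", length(starts))

  for (s in seq_along(starts)) {
    ages <- starts[s] + 0:(H - 1)
    i_tot <- schedule_lookup(config$incidence, ages, "rate_low_income")
    dec_share <- schedule_lookup(config$incidence, ages, "deciduous_share")
    mort <- schedule_lookup(config$mortality, ages, "combined")
    other_pc <- vapply(ages, expected_other_cost_per_case,
                       numeric(1), costs = costs,
                       scenario = config$scenario,
                       include_hospitalisation = config$include_hospitalisation,
                       symptomatic_fraction = sf)

    occ <- c(caries_free = subsize, caries = 0, edentulous = 0, dead = 0)
    tab <- matrix(0, nrow = H, ncol = 16L)
    colnames(tab) <- c(health_states,
                       paste0("py_", health_states),
                       "cases_deciduous", "cases_permanent",
                       "decayed_teeth", "cost_intervention",
                       "cost_healthcare", "dalys", "qalys", "deaths")

    for (t in seq_len(H)) {
      i_dec <- i_tot[t] * dec_share[t]
      i_perm <- i_tot[t] * (1 - dec_share[t])
      if (!is.null(intervention)) {
        adj <- adjust_incidence(intervention, i_dec, i_perm,
                                occlusal_share = occl,
                                teeth_per_case = tpc,
                                effect = draw$effect)
        i_dec <- adj[[1L]]; i_perm <- adj[[2L]]
      }
      step <- transition_step(occ, i_dec, i_perm, mort[t],
                              recovery = recovery)
      cases <- step$cases_deciduous + step$cases_permanent
      py <- if (cycle_correction == "half_cycle") {
        (occ + step$occupancy) / 2
      } else occ
      int_cost <- if (is.null(intervention)) 0 else {
        subsize * per_child_intervention_cost(
          intervention, costs, t - 1L, travel_cost = draw$travel_cost)
      }
      tab[t, ] <- c(occ, py,
                    step$cases_deciduous, step$cases_permanent,
                    cases * tpc, int_cost,
                    cases * (per_treat + other_pc[t]),
                    cases * per_yld, cases * per_qaly,
                    step$occupancy[["dead"]] - occ[["dead"]])
      occ <- step$occupancy
    }

    df <- data.frame(start_age = starts[s], cycle = 0:(H - 1),
                     age = ages, tab, row.names = NULL)
    for (col in c("cases_deciduous", "cases_permanent", "decayed_teeth",
                  "cost_intervention", "cost_healthcare", "dalys",
                  "qalys")) {
      df[[paste0("disc_", col)]] <- df[[col]] * disc_f
    }
    blocks[[s]] <- df
  }

  trace <- do.call(rbind, blocks)
  trace$cases <- trace$cases_deciduous + trace$cases_permanent
  trace$disc_cases <- trace$disc_cases_deciduous + trace$disc_cases_permanent
  trace$cost_total <- trace$cost_intervention + trace$cost_healthcare
  trace$disc_cost_total <- trace$disc_cost_intervention +
    trace$disc_cost_healthcare

  tot <- function(col) sum(trace[[col]])
  totals <- c(
    cases = tot("cases"), decayed_teeth = tot("decayed_teeth"),
    dalys = tot("dalys"), qalys = tot("qalys"),
    cost_intervention = tot("cost_intervention"),
    cost_healthcare = tot("cost_healthcare"),
    cost_total = tot("cost_total"),
    disc_cases = tot("disc_cases"),
    disc_decayed_teeth = tot("disc_decayed_teeth"),
    disc_dalys = tot("disc_dalys"), disc_qalys = tot("disc_qalys"),
    disc_cost_intervention = tot("disc_cost_intervention"),
    disc_cost_healthcare = tot("disc_cost_healthcare"),
    disc_cost_total = tot("disc_cost_total"))

  structure(
    list(trace = trace, totals = totals,
         meta = list(arm = if (is.null(intervention)) "comparator"
                     else intervention$id,
                     scenario = config$scenario,
                     horizon_years = H, recovery = recovery,
                     cycle_correction = cycle_correction,
                     cohort = config$cohort$label)),
    class = "cycle_trace")
}

#' @export
print.cycle_trace <- function(x, ...) {
  cat(sprintf("<cycle_trace> %s arm, %s, %d cycles\n",
              x$meta$arm, x$meta$scenario, x$meta$horizon_years))
  cat(sprintf("  cohort: %s\n", x$meta$cohort))
  t <- x$totals
  cat(sprintf("  cases %.0f | DT %.0f | DALYs %.2f | QALYs lost %.2f\n",
              t[["cases"]], t[["decayed_teeth"]], t[["dalys"]],
              t[["qalys"]]))
  cat(sprintf("  cost AUD %.2fM (intervention %.2fM, healthcare %.2fM), discounted %.2fM\n",
              t[["cost_total"]] / 1e6, t[["cost_intervention"]] / 1e6,
              t[["cost_healthcare"]] / 1e6, t[["disc_cost_total"]] / 1e6))
  invisible(x)
}

#' @export
as.data.frame.cycle_trace <- function(x, ...) x$trace

#' Export a cycle trace as tidy CSV
#'
#' One row per sub-cohort, cycle and state with occupancy and
#' half-cycle-corrected person-years, for external inspection.
#'
#' @param trace A `cycle_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- trace$trace
  long <- do.call(rbind, lapply(health_states, function(st) {
    data.frame(start_age = df$start_age, cycle = df$cycle, age = df$age,
               state = st, occupancy = df[[st]],
               person_years = df[[paste0("py_", st)]])
  }))
  write.csv(long[order(long$start_age, long$cycle), ], path,
            row.names = FALSE)
  invisible(path)
}

#' Incremental outcomes of an intervention arm versus the comparator
#'
#' Differences in the conventional signs of a cost-effectiveness table:
#' `delta_cost` is intervention minus comparator total cost (program cost
#' net of averted healthcare costs), while `delta_dt`, `delta_daly` and
#' `delta_qaly` are comparator minus intervention (decayed teeth prevented,
#' DALYs averted, QALYs gained).
#'
#' @param comparator,intervention `cycle_trace` objects from
#'   [run_cohort()].
#' @return List with `discounted` and `undiscounted` named vectors.
#' @export
incremental_outcomes <- function(comparator, intervention) {
  ct <- comparator$totals; it <- intervention$totals
  delta <- function(prefix) {
    c(delta_cost = it[[paste0(prefix, "cost_total")]] -
        ct[[paste0(prefix, "cost_total")]],
      delta_dt = ct[[paste0(prefix, "decayed_teeth")]] -
        it[[paste0(prefix, "decayed_teeth")]],
      delta_daly = ct[[paste0(prefix, "dalys")]] -
        it[[paste0(prefix, "dalys")]],
      delta_qaly = ct[[paste0(prefix, "qalys")]] -
        it[[paste0(prefix, "qalys")]])
  }
  list(discounted = delta("disc_"), undiscounted = delta(""))
}
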