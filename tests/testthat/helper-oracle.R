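# Independent loop-based reference engine.  Everything is recomputed with
# plain scalar arithmetic: own interpolation, own transition updates, own
# fee-schedule arithmetic and own discounting, so agreement with
# run_cohort() is a genuine cross-check rather than a tautology.

ref_interp <- function(tab, col, age) {
  i <- findInterval(age, tab$age)
  if (i >= nrow(tab)) return(tab[[col]][nrow(tab)])
  x0 <- tab$age[i]; x1 <- tab$age[i + 1]
  y0 <- tab[[col]][i]; y1 <- tab[[col]][i + 1]
  y0 + (y1 - y0) * (age - x0) / (x1 - x0)
}

# Per-child program cost re-derived from the published fee schedules.
ref_child_cost <- function(id, costs, year, travel) {
  if (id == "1a") {
    if (year > 5) return(0)
    visits <- if (year == 0) 1 else 2
    visits * (costs$home_visit_consult + travel)
  } else if (id == "1b") {
    if (year > 5) return(0)
    visits <- if (year == 0) 1 else 2
    visits * costs$telehealth_consult
  } else if (id == "2a") {
    if (year > 1) return(0)
    2 * costs$varnish_fee + if (year == 0) costs$screening_fee else 0
  } else if (id == "2b") {
    if (year > 1) return(0)
    2 * costs$varnish_fee * costs$stepdown_factor
  } else if (id == "3") {
    if (year > 0) return(0)
    costs$screening_fee + 4 * costs$sealant_fee_per_tooth
  } else stop("unknown id")
}

ref_cohort_totals <- function(config, spec = NULL, draw = NULL) {
  v <- config$valuation
  costs <- config$costs
  pick <- function(x, default) if (is.null(x)) default else x
  dw <- pick(draw$disability_weight, v$disability_weight$mean)
  ug <- pick(draw$utility_gain, v$utility_gain)
  tpc <- pick(draw$teeth_per_case, v$teeth_per_case$mean)
  fee_chk <- pick(draw$checkup_fee, costs$checkup_fee$mean)
  fee_res <- pick(draw$restoration_fee, costs$restoration_fee_per_tooth$mean)
  travel <- pick(draw$travel_cost, costs$home_visit_travel$mean)
  sf <- v$symptomatic_fraction$default
  dur <- v$episode_duration_days
  r <- config$econ$discount_rate_per_year
  occl <- attr(config$incidence, "occlusal_molar_share")
  H <- config$horizon_years
  starts <- config$cohort$start_ages
  n0 <- config$cohort$size_low_income / length(starts)

  acc <- setNames(numeric(12),
                  c("cases", "dt", "daly", "qaly", "ci", "ch",
                    "d_cases", "d_dt", "d_daly", "d_qaly", "d_ci", "d_ch"))
  for (a0 in starts) {
    s_cf <- n0; s_ca <- 0; s_ed <- 0; s_de <- 0
    for (t in 0:(H - 1)) {
      age <- a0 + t
      itot <- ref_interp(config$incidence, "rate_low_income", age)
      shr <- ref_interp(config$incidence, "deciduous_share", age)
      m <- ref_interp(config$mortality, "combined", age)
      idec <- itot * shr
      iperm <- itot * (1 - shr)
      if (!is.null(spec)) {
        eff <- pick(draw$effect, spec$effect)
        if (spec$effect_kind == "ABS_DMFT_REDUCTION") {
          idec <- max(0, idec -
                        abs(eff$delta_dmft) / tpc / spec$effect_window_years)
        } else if (spec$effect_kind == "PREVENTIVE_FRACTION") {
          idec <- idec * (1 - eff$pf_deciduous)
          iperm <- iperm * (1 - eff$pf_permanent)
        } else if (spec$effect_kind == "ODDS_RATIO") {
          po <- iperm * occl
          iperm <- iperm - po +
            eff$odds_ratio * po / (1 - po + eff$odds_ratio * po)
        }
      }
      cases <- s_cf * (1 - m) * (idec + iperm)
      new_cf <- s_cf * (1 - m) * (1 - idec - iperm) + s_ca * (1 - m)
      new_de <- s_de + m * (s_cf + s_ca + s_ed)
      s_ed <- s_ed * (1 - m)
      s_ca <- cases
      s_cf <- new_cf
      s_de <- new_de

      oc <- 0
      if (config$scenario %in% c("other_healthcare_costs",
                                 "extrapolation_12y")) {
        pw <- costs$public_sector_weight
        for (it in costs$other_items) {
          oc <- oc + pw * it$public_fee + (1 - pw) * it$private_fee
        }
        if (config$include_hospitalisation && age < 7) {
          oc <- oc + sf * (costs$hospitalisation_cost + costs$ga_cost)
        }
      }
      treat <- costs$treatment_access_prob * (fee_chk + tpc * fee_res)
      ic <- if (is.null(spec)) 0 else {
        n0 * ref_child_cost(spec$id, costs, t, travel)
      }
      dfac <- (1 + r)^(-t)
      add <- c(cases, cases * tpc,
               cases * dw * sf * dur / 365, cases * ug * sf * dur / 365,
               ic, cases * (treat + oc))
      acc <- acc + c(add, add * dfac)
    }
  }
  acc
}

# run_cohort totals in the reference order, for comparison
engine_totals_vec <- function(trace) {
  t <- trace$totals
  c(t[["cases"]], t[["decayed_teeth"]], t[["dalys"]], t[["qalys"]],
    t[["cost_intervention"]], t[["cost_healthcare"]],
    t[["disc_cases"]], t[["disc_decayed_teeth"]], t[["disc_dalys"]],
    t[["disc_qalys"]], t[["disc_cost_intervention"]],
    t[["disc_cost_healthcare"]])
}
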