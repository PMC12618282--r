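# The five modelled preventive interventions: effect transforms on
# incidence, visit schedules and per-child cost streams.

intervention_ids <- c("1a", "1b", "2a", "2b", "3")

#' Specification of a preventive intervention
#'
#' Returns the built-in specification for one of the five modelled
#' interventions, holding its effect transform, effect sizes with sampling
#' uncertainty, target dentition, visit/cost schedule and provider.
#'
#' * `"1a"` - anticipatory guidance by oral health therapists via home
#'   visits: absolute reduction of -0.15 in mean deciduous caries increment
#'   (dmft) over the 6-year window; 11 visits (1 in year one, then 2/year).
#' * `"1b"` - anticipatory guidance via telehealth: -0.18 dmft, same visit
#'   schedule at the telehealth consultation fee.
#' * `"2a"` - school-based six-monthly fluoride varnish by dental
#'   practitioners: preventive fraction 0.37 (deciduous) / 0.43 (permanent),
#'   screening at the first visit, four visits over 2 years.
#' * `"2b"` - as 2a but applied by non-dental health professionals at a
#'   step-down fee, no screening; identical effectiveness to 2a.
#' * `"3"` - school-based fissure sealants on all four first or second
#'   permanent molars, one visit with screening: odds ratio 0.12 applied to
#'   the occlusal-molar share of permanent-teeth incidence.
#'
#' Effect sizes act at 100% in every cycle (0% annual decay); only the cost
#' stream is limited to the program window.  Effect-size standard
#' deviations are package defaults for the probabilistic analysis, taken
#' from the source meta-analyses' interval estimates where available.
#'
#' @param id One of `"1a"`, `"1b"`, `"2a"`, `"2b"`, `"3"`.
#' @return An `intervention_spec` list.
#' @export
#' @examples
#' intervention_spec("2a")$effect
intervention_spec <- function(id = intervention_ids) {
  id <- match.arg(id)
  base <- switch(id,
    "1a" = list(
      label = "Anticipatory guidance (home visits)",
      effect_kind = "ABS_DMFT_REDUCTION",
      effect = list(delta_dmft = -0.15, sd = 0.030),
      target = "deciduous",
      effect_window_years = 6,
      cost_window_years = 6,
      visits_per_year = c(1, 2, 2, 2, 2, 2),
      includes_screening_first_visit = FALSE,
      provider = "oral_health_therapist",
      printed_first_year_cost_m = 1.6),
    "1b" = list(
      label = "Anticipatory guidance (telehealth)",
      effect_kind = "ABS_DMFT_REDUCTION",
      effect = list(delta_dmft = -0.18, sd = 0.036),
      target = "deciduous",
      effect_window_years = 6,
      cost_window_years = 6,
      visits_per_year = c(1, 2, 2, 2, 2, 2),
      includes_screening_first_visit = FALSE,
      provider = "oral_health_therapist",
      printed_first_year_cost_m = 0.7),
    "2a" = list(
      label = "Dental screening and fluoride varnish",
      effect_kind = "PREVENTIVE_FRACTION",
      effect = list(pf_deciduous = 0.37, sd_deciduous = 0.068,
                    pf_permanent = 0.43, sd_permanent = 0.069),
      target = "both_dentitions",
      effect_window_years = 2,
      cost_window_years = 2,
      visits_per_year = c(2, 2),
      includes_screening_first_visit = TRUE,
      provider = "dental_practitioner",
      # Published first-year program cost; the fee schedule arithmetic
      # gives $34.3M - both are exposed, the model uses the fee formula.
      printed_first_year_cost_m = 34.6),
    "2b" = list(
      label = "Fluoride varnish (non-dental health professionals)",
      effect_kind = "PREVENTIVE_FRACTION",
      effect = list(pf_deciduous = 0.37, sd_deciduous = 0.068,
                    pf_permanent = 0.43, sd_permanent = 0.069),
      target = "both_dentitions",
      effect_window_years = 2,
      cost_window_years = 2,
      visits_per_year = c(2, 2),
      includes_screening_first_visit = FALSE,
      provider = "non_dental_professional",
      printed_first_year_cost_m = 18.9),
    "3" = list(
      label = "Dental screening and fissure sealant",
      effect_kind = "ODDS_RATIO",
      effect = list(odds_ratio = 0.12, sd = 0.028),
      target = "occlusal_molars",
      effect_window_years = 2,
      cost_window_years = 1,
      visits_per_year = 1,
      includes_screening_first_visit = TRUE,
      provider = "dental_practitioner",
      printed_first_year_cost_m = 21.2))
  spec <- c(list(id = id), base, list(decay_rate_per_year = 0))
  validate_intervention_spec(structure(spec, class = "intervention_spec"))
}

validate_intervention_spec <- function(spec) {
  chk(spec$id %in% intervention_ids, "id", "unknown intervention id")
  chk(spec$effect_kind %in% c("ABS_DMFT_REDUCTION", "PREVENTIVE_FRACTION",
                              "ODDS_RATIO"), "effect_kind",
      "unknown effect transform")
  if (spec$effect_kind == "PREVENTIVE_FRACTION") {
    chk(is_prob(spec$effect$pf_deciduous) && is_prob(spec$effect$pf_permanent),
        "effect", "preventive fractions must be in [0, 1]")
  }
  if (spec$effect_kind == "ODDS_RATIO") {
    chk(is_number(spec$effect$odds_ratio) && spec$effect$odds_ratio > 0,
        "effect", "odds ratio must be > 0")
  }
  if (spec$effect_kind == "ABS_DMFT_REDUCTION") {
    chk(is_number(spec$effect$delta_dmft) && spec$effect$delta_dmft <= 0,
        "effect", "delta_dmft must be <= 0 (a reduction)")
  }
  chk(is_prob(spec$decay_rate_per_year), "decay_rate_per_year",
      "must be in [0, 1]")
  chk(!spec$includes_screening_first_visit ||
        spec$id %in% c("2a", "3"),
      "includes_screening_first_visit",
      "screening costs apply to interventions 2a and 3 only")
  chk(length(spec$visits_per_year) == spec$cost_window_years,
      "visits_per_year", "must list one entry per cost-window year")
  invisible(spec)
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf("<intervention_spec %s> %s\n", x$id, x$label))
  cat(sprintf("  effect : %s on %s\n", x$effect_kind, x$target))
  cat(sprintf("  costs  : %d-year window, visits/year %s\n",
              x$cost_window_years,
              paste(x$visits_per_year, collapse = ", ")))
  invisible(x)
}

# ---- effect transforms -----------------------------------------------------

#' Apply a preventive fraction to an incidence rate
#'
#' `rate * (1 - pf)`: the preventive fraction is the proportional reduction
#' in incidence attributable to the intervention.
#'
#' @param rate Baseline per-person annual case probability in `[0, 1]`.
#' @param pf Preventive fraction in `[0, 1]`.
#' @return Adjusted probability.
#' @export
#' @examples
#' apply_preventive_fraction(0.2, 0.37)  # 0.126
apply_preventive_fraction <- function(rate, pf) {
  chk(all(rate >= 0 & rate <= 1), "rate", "must be in [0, 1]")
  chk(all(pf >= 0 & pf <= 1), "pf", "must be in [0, 1]")
  rate * (1 - pf)
}

#' Convert a baseline risk through an odds ratio
#'
#' `p1 = OR * p0 / (1 - p0 + OR * p0)`: the intervention-arm risk implied
#' by an odds ratio at baseline risk `p0`.  In the model this transform is
#' applied only to the occlusal-molar share of permanent-teeth incidence,
#' the surfaces a fissure sealant protects.
#'
#' @param p0 Baseline probability, `0 <= p0 < 1`.
#' @param or_value Odds ratio, `> 0`.
#' @return Adjusted probability.
#' @export
#' @examples
#' odds_ratio_to_adjusted_risk(0.10, 0.12)  # 0.013158
odds_ratio_to_adjusted_risk <- function(p0, or_value) {
  chk(all(p0 >= 0), "p0", "must be >= 0")
  if (any(p0 >= 1)) fail_field("p0", "degenerate baseline risk p0 >= 1")
  chk(all(or_value > 0), "or_value", "must be > 0")
  or_value * p0 / (1 - p0 + or_value * p0)
}

#' Convert a cumulative dmft reduction into a per-cycle case reduction
#'
#' The anticipatory-guidance trials report a cumulative difference in mean
#' deciduous caries increment (dmft) over the intervention window.  Dividing
#' by the mean decayed teeth per case converts teeth to cases, and spreading
#' uniformly over the window gives an absolute per-cycle reduction in the
#' per-person case probability, applied to deciduous incidence only (the
#' adjusted incidence is floored at zero by the engine).
#'
#' @param delta_dmft Cumulative mean dmft difference, `<= 0`.
#' @param teeth_per_case Mean decayed teeth per incident case, `> 0`.
#' @param window_years Years the trial effect accrued over, `> 0`.
#' @return Per-cycle case-probability reduction (positive number).
#' @export
#' @examples
#' anticipatory_guidance_case_reduction(-0.15, 1.64, 6)  # 0.01524...
anticipatory_guidance_case_reduction <- function(delta_dmft, teeth_per_case,
                                                 window_years) {
  chk(all(delta_dmft <= 0), "delta_dmft", "must be <= 0 (a reduction)")
  chk(all(teeth_per_case > 0), "teeth_per_case", "must be > 0")
  chk(all(window_years > 0), "window_years", "must be > 0")
  abs(delta_dmft) / teeth_per_case / window_years
}

# Apply an intervention's effect transform to the (deciduous, permanent)
# incidence pair at one age.  `effect` allows a PSA draw to override the
# spec's mean effect values; `teeth_per_case` is needed by the dmft
# conversion and may itself be a draw.
adjust_incidence <- function(spec, rate_deciduous, rate_permanent,
                             occlusal_share, teeth_per_case,
                             effect = NULL) {
  eff <- if (is.null(effect)) spec$effect else effect
  switch(spec$effect_kind,
    ABS_DMFT_REDUCTION = {
      red <- anticipatory_guidance_case_reduction(
        min(eff$delta_dmft, 0), teeth_per_case, spec$effect_window_years)
      if (red > rate_deciduous && rate_deciduous > 0) {
        warning("dmft-derived reduction exceeds baseline deciduous ",
                "incidence; clipping to zero incidence", call. = FALSE)
      }
      c(max(0, rate_deciduous - red), rate_permanent)
    },
    PREVENTIVE_FRACTION = {
      c(apply_preventive_fraction(rate_deciduous,
                                  min(1, max(0, eff$pf_deciduous))),
        apply_preventive_fraction(rate_permanent,
                                  min(1, max(0, eff$pf_permanent))))
    },
    ODDS_RATIO = {
      occ <- rate_permanent * occlusal_share
      occ_adj <- odds_ratio_to_adjusted_risk(occ, eff$odds_ratio)
      c(rate_deciduous, rate_permanent - occ + occ_adj)
    })
}

# ---- cost stream -----------------------------------------------------------

per_child_intervention_cost <- function(spec, costs, year_index,
                                        travel_cost = NULL) {
  chk(is_number(year_index) && year_index >= 0, "year_index",
      "must be >= 0")
  if (year_index >= spec$cost_window_years) return(0)
  visits <- spec$visits_per_year[year_index + 1L]
  if (is.null(travel_cost)) travel_cost <- costs$home_visit_travel$mean
  per_visit <- switch(spec$id,
    "1a" = costs$home_visit_consult + travel_cost,
    "1b" = costs$telehealth_consult,
    "2a" = costs$varnish_fee,
    "2b" = costs$varnish_fee * costs$stepdown_factor,
    "3"  = 4 * costs$sealant_fee_per_tooth)
  screening <- if (spec$includes_screening_first_visit && year_index == 0)
    costs$screening_fee else 0
  visits * per_visit + screening
}

#' Program cost for one model year
#'
#' Total intervention delivery cost in a given year: the per-child cost for
#' that year's visit schedule (screening added at the first visit where the
#' program includes it; the step-down reimbursement applied for non-dental
#' providers) times the enrolled low-income cohort.  Zero beyond the
#' program's cost window.
#'
#' @param spec An [intervention_spec()].
#' @param costs A [cost_params()].
#' @param cohort A [cohort_spec()].
#' @param year_index Model year, 0-based.
#' @return Cost in AUD.
#' @export
#' @examples
#' intervention_cost_for_year(intervention_spec("3"), cost_params(),
#'                            cohort_spec(c(6, 12), 94025, 638445), 0)
intervention_cost_for_year <- function(spec, costs, cohort, year_index) {
  cohort$size_low_income *
    per_child_intervention_cost(spec, costs, year_index)
}
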