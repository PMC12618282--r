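# Per-case valuation: decayed teeth, DALYs, QALYs and healthcare costs for
# one incident dental caries episode.  Disability and utility amounts
# accrue per episode (a short symptomatic event within the cycle), not per
# occupancy-year, and caries carries no mortality, so the DALY is pure
# years lived with disability.

#' Years lived with disability per incident case
#'
#' `disability_weight * symptomatic_fraction * episode_duration / 365`:
#' only symptomatic cases accrue disability, and only for the episode
#' duration.  With the default parameters (weight 0.010, 14.7% symptomatic,
#' 28 days) this is about 1.13e-4 DALY per case.
#'
#' @param valuation An [episode_valuation()].
#' @param disability_weight,symptomatic_fraction Optional overrides (e.g. a
#'   PSA draw or an age-specific symptomatic proportion).
#' @return DALYs per case.
#' @export
yld_per_case <- function(valuation, disability_weight = NULL,
                         symptomatic_fraction = NULL) {
  dw <- disability_weight %||% valuation$disability_weight$mean
  sf <- symptomatic_fraction %||% valuation$symptomatic_fraction$default
  dw * sf * valuation$episode_duration_days / 365
}

#' QALY gain per case prevented
#'
#' Mirrors [yld_per_case()] with the utility gain in place of the
#' disability weight: `utility_gain * symptomatic_fraction *
#' episode_duration / 365`.  The per-case QALY:DALY ratio is therefore
#' exactly `utility_gain / disability_weight` (5 at the defaults).
#'
#' @inheritParams yld_per_case
#' @param utility_gain Optional override of the valuation's utility gain.
#' @return QALYs per case.
#' @export
qaly_gain_per_case <- function(valuation, utility_gain = NULL,
                               symptomatic_fraction = NULL) {
  ug <- utility_gain %||% valuation$utility_gain
  sf <- symptomatic_fraction %||% valuation$symptomatic_fraction$default
  ug * sf * valuation$episode_duration_days / 365
}

#' Expected dental treatment cost per incident case
#'
#' `treatment_access_prob * (checkup_fee + teeth_per_case *
#' restoration_fee_per_tooth)`: a case that reaches care incurs one
#' check-up plus one restoration per decayed tooth; only the accessing
#' fraction of cases incurs these costs.
#'
#' @param costs A [cost_params()].
#' @param valuation An [episode_valuation()].
#' @param checkup_fee,restoration_fee,teeth_per_case Optional overrides
#'   (PSA draws).
#' @return AUD per case.
#' @export
treatment_cost_per_case <- function(costs, valuation, checkup_fee = NULL,
                                    restoration_fee = NULL,
                                    teeth_per_case = NULL) {
  cf <- checkup_fee %||% costs$checkup_fee$mean
  rf <- restoration_fee %||% costs$restoration_fee_per_tooth$mean
  tpc <- teeth_per_case %||% valuation$teeth_per_case$mean
  costs$treatment_access_prob * (cf + tpc * rf)
}

#' Other healthcare costs per case (sensitivity scenario)
#'
#' Extra per-case costs switched on by the `other_healthcare_costs` and
#' 12-year extrapolation scenarios: a sector-weighted fee list (pulp
#' therapy, extractions, ...; public share `public_sector_weight`, private
#' share its complement) for every case, plus the potentially preventable
#' hospitalisation and dental general anaesthesia costs, which accrue only
#' for children under 7 years experiencing toothache.  Returns 0 in the
#' base case.
#'
#' @param costs A [cost_params()].
#' @param age Age in years at the cycle.
#' @param toothache Whether the case is symptomatic (the engine weights
#'   the hospitalisation component by the symptomatic fraction instead of
#'   passing a flag).
#' @param scenario Model scenario string.
#' @return AUD per case.
#' @export
other_healthcare_cost_per_case <- function(costs, age, toothache = FALSE,
                                           scenario = "base_case") {
  if (!scenario %in% c("other_healthcare_costs", "extrapolation_12y")) {
    return(0)
  }
  pw <- costs$public_sector_weight
  items <- sum(vapply(costs$other_items, function(it) {
    pw * it$public_fee + (1 - pw) * it$private_fee
  }, numeric(1)))
  hosp <- if (age < 7 && isTRUE(toothache)) {
    costs$hospitalisation_cost + costs$ga_cost
  } else 0
  items + hosp
}

# Expected extra cost per case used by the engine: the hospitalisation
# component is weighted by the probability of toothache (the symptomatic
# fraction) and gated on the config's hospitalisation flag.
expected_other_cost_per_case <- function(costs, age, scenario,
                                         include_hospitalisation,
                                         symptomatic_fraction) {
  base <- other_healthcare_cost_per_case(costs, age, toothache = FALSE,
                                         scenario = scenario)
  extra <- if (include_hospitalisation) {
    symptomatic_fraction *
      (other_healthcare_cost_per_case(costs, age, toothache = TRUE,
                                      scenario = scenario) - base)
  } else 0
  base + extra
}

#' Convert incident cases to decayed teeth
#'
#' `cases * teeth_per_case` (default 1.64 decayed teeth per case).
#'
#' @param cases Number of incident cases, `>= 0`.
#' @param valuation An [episode_valuation()].
#' @param teeth_per_case Optional override (PSA draw).
#' @return Decayed teeth.
#' @export
cases_to_decayed_teeth <- function(cases, valuation, teeth_per_case = NULL) {
  chk(all(cases >= 0), "cases", "must be >= 0")
  tpc <- teeth_per_case %||% valuation$teeth_per_case$mean
  cases * tpc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
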