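---
title: "Methods: closed-cohort modelling of dental caries prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-cohort modelling of dental caries prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariescea)
```

This vignette is the package's own account of its model: the structure and
assumptions, the parameters that matter, what the synthetic epidemiology
generator does and does not emulate, the numerical choices, and the design
decisions that were genuinely open.

## The decision problem

Five preventive programs for childhood dental caries are compared against a
no-intervention comparator for Australian children from low-income
households, from a government healthcare perspective in 2020 AUD:
anticipatory guidance by oral health therapists delivered at home (1a) or by
telehealth (1b) from age six months; school-based six-monthly fluoride
varnish by dental practitioners (2a) or non-dental health professionals
(2b) for ages 6–12; and school-based fissure sealants on the four first or
second permanent molars at ages 6 and 12 (3).  Outcomes are decayed teeth
(DT) prevented, DALYs averted and QALYs gained; cost-effectiveness is
judged by net monetary benefit at AUD 50,000 per DALY averted and
AUD 28,033 per QALY gained.

## Cohort model

Each intervention's target population enters as a closed cohort — one or
more single-year-of-age sub-cohorts with the low-income population split
evenly across start ages, no new entrants — and is propagated in one-year
cycles through four states: *caries free*, *dental caries*, *edentulous*
and *dead*.

Assumptions:

* **Expected-value propagation.**  Occupancy is deterministic and
  fractional; all stochastics live in the probabilistic sensitivity
  analysis (PSA).  This matches cohort-model semantics and makes the
  comparator arm bit-reproducible.
* **Competing risks within a cycle.**  Background mortality applies first
  to every alive state; incident caries then arises among surviving
  caries-free members with the summed deciduous + permanent probability.
  At child mortality levels (~10⁻³–10⁻⁴/year) the ordering is numerically
  irrelevant, but it is fixed and documented so the engine is exactly
  reproducible by the independent reference implementation in the test
  suite.
* **One case per person per year.**  Incidence is a per-person annual
  probability; multiple episodes in a cycle are excluded.  Decayed-teeth
  counts come from the teeth-per-case multiplier, not repeated
  transitions.
* **Caries-state dwell.**  The published prior model's dwell structure is
  not restated, so both readings are implemented: the default returns an
  incident case to *caries free* after one cycle (the episode is treated
  or arrests — consistent with valuing short episodes rather than chronic
  occupancy), and an `"until_treated"` absorbing-until-death alternative
  is selectable.  All shipped results use the one-cycle policy.
* **Edentulism.**  Entry is zero at every modelled age (it only accrues
  from age 20+); the state is retained for structural fidelity but never
  populated, and carries no valuation.
* **No years of life lost.**  Caries is nonfatal in the model; *dead*
  arises only from background mortality, so the DALY is pure YLD.
* **Half-year start ages.**  The six-month cohort is mapped to the cycle
  grid as age 0.5→1.5 in cycle 0, keeping one-year cycles exact;
  schedules are linearly interpolated at half-ages.
* **Within-cycle correction.**  Occupancy person-years are reported as the
  trapezoid (half-cycle) average of start- and end-of-cycle occupancy by
  default (`"none"` selectable).  Incident-event accumulators — cases,
  decayed teeth, episode DALYs/QALYs, per-case costs — count events
  directly and need no correction.
* **Discounting.**  `x/(1+r)^t` with cycle 0 undiscounted, r = 3%/year
  for both costs and health outcomes.

## Intervention effects

Effects act on the dentition-specific incidence rates at 100% in every
cycle (a 0% annual decay), while costs are confined to each program's
window.  The effect-window metadata records the duration the evidence
covers; under the 12-year extrapolation the effect simply continues, which
reproduces the published design (effectiveness "the same when
extrapolated", costs fixed to six/two years).

* **Anticipatory guidance (1a, 1b).**  The trials report cumulative mean
  deciduous caries-increment (dmft) differences of −0.15 (home visits) and
  −0.18 (telehealth) over six years.  The conversion to a per-cycle
  absolute case-probability reduction is `|Δdmft| / teeth_per_case /
  window`, applied to deciduous incidence only and floored at zero
  incidence (with a warning when the floor binds).  The conversion is
  deliberately isolated in one function
  (`anticipatory_guidance_case_reduction()`) because the original
  decision-software derivation is not reproducible verbatim; uniform
  spreading over the window is the neutral choice.  Note a useful consequence: the
  teeth-per-case draw cancels between the conversion (teeth → cases) and
  the DT accrual (cases → teeth), so the teeth *prevented* by these arms
  are pinned to the trial effect — which is exactly what the trial
  measured.
* **Fluoride varnish (2a, 2b).**  Preventive fractions 0.37 (deciduous)
  and 0.43 (permanent) multiply the respective rates by `1 − PF`.  The
  published table's row layout is ambiguous about which fraction belongs
  to which delivery mode, but the published results show both arms with
  identical effectiveness cells, so both fractions are applied to both
  arms; the arms differ only in cost (screening at the first 2a visit;
  2b at a 76.9% step-down reimbursement, no screening).
* **Fissure sealants (3).**  The odds ratio 0.12 is converted to an
  adjusted risk `OR·p₀/(1 − p₀ + OR·p₀)` and applied only to the share of
  permanent-teeth incidence arising on occlusal surfaces of the
  first/second permanent molars — the surfaces a sealant covers.  That
  share is not published; the default is 0.5 of permanent incidence and
  is configurable (`occlusal_molar_share`).

## Episode valuation

DALYs and QALYs accrue per incident episode, not per occupancy-year: a
case is symptomatic with probability equal to the symptomatic fraction,
for 28 days.  Hence

* `DALY/case = DW × sf × 28/365`, disability weight DW = 0.010 (SD 0.004);
* `QALY/case = g × sf × 28/365`, utility gain g = (1 − 0.9)/2 = 0.05,
  the halved complement of the 0.9 caries health-state utility (halving
  reflects that a child free of caries is not thereby in perfect health);
* the symptomatic fraction is published only as a range, 8.4–21.0%; it is
  stored as an age-resolvable range with the midpoint 0.147 as the single
  default, since no age-specific values are available.

Per-case healthcare cost is `access × (check-up + teeth_per_case ×
restoration)` with a mean of 1.64 decayed teeth per case.  The treatment
access probability — the fraction of incident cases that incur check-up
and restoration costs in the year of onset — is not published; the
published incremental-cost cells imply treatment costs accrue to only a
small fraction of cases, and the default is set once at 0.12, consistent
with limited restorative access among low-income children.  It is a
`cost_params()` field, not a constant.

The *other healthcare costs* scenario adds a config-driven fee list (pulp
therapy, extractions; synthetic illustrative defaults) weighted 15%
public / 85% private, plus hospitalisation (dental extraction and
restoration admission) and general anaesthesia costs that accrue only to
symptomatic cases under age 7 — and only in the anticipatory-guidance
cohorts, whose trial supplied those costs.  The 12-year extrapolation
scenario includes these items as well.

## Synthetic epidemiology

The real model was driven by national burden-of-disease incidence, census
cohort counts and life tables; only the cohort counts are published.  The
generator therefore supplies the missing schedules with the statistical
structure the model assumes:

* per-age annual caries-case probability = `base_rate × age shape ×
  lognormal noise`, clipped to [0, 1]; a low-income rate = `min(1,
  general × low_income_ratio)` with ratio default 1.5 (≥ 1 by contract);
* a deciduous share of 1 up to age 5 declining linearly to 0 at age 14
  (the mixed-dentition window), so deciduous + permanent always sum to the
  total;
* U-shaped background mortality scaled by a level parameter, with a fixed
  1.3 male:female hazard ratio and a 0.512 male cohort share (mortality,
  not incidence, is sex-differentiated).

The default age shape is bimodal: a flat early-childhood plateau
(deciduous disease), a trough at ages 6–7 as primary teeth begin to
exfoliate, a secondary peak near ages 8–10 as newly erupted first
permanent molars accumulate caries, and low adolescent rates.  With the
default base rate 0.15/year, general-population rates span roughly
0.05–0.19/year over ages 1–14.  The shape was calibrated once — against
the published program-cost schedules and cohort sizes — so that
prevented-case counts, and therefore the cost-per-DT ordering of the five
programs, land on the order reported for the Australian low-income child
population; it was frozen before the test suite was finalised and is not
adjusted per run.  Every generated schedule is deterministic in its seed.

What the generator does *not* emulate: real dentition-specific national
incidence levels (it produces one total rate split by a stylised eruption
profile), the empirical low-income adjustment from national survey data,
geographic or Indigenous-status heterogeneity, secular trends, and any
correlation between incidence and mortality.  Passing tests therefore
demonstrate the *method* — transforms, accounting, uncertainty
propagation and ranking behaviour under a realistic rate structure — not
a forecast for the actual population; substituting real schedules via the
CSV interface is the intended path for applied estimates.

## Probabilistic sensitivity analysis

2,000 Monte Carlo iterations per intervention (configurable).  The
published description ("Monte Carlo simulation with 2,000 cycles") is
read as 2,000 PSA iterations, distinct from the Markov cycles: the
reported standard errors imply repeated sampling, and within-cycle
correction belongs to the cohort engine.

Per iteration one parameter set is drawn and shared by both arms (common
random numbers, so incremental outcomes reflect parameter uncertainty
only).  Families are normal with truncation by resampling:

| parameter | mean (SD) | truncation |
|---|---|---|
| Δdmft, 1a / 1b | −0.15 (0.030) / −0.18 (0.036) | ≤ 0 |
| PF deciduous / permanent | 0.37 (0.068) / 0.43 (0.069) | [0, 1] |
| odds ratio, sealants | 0.12 (0.028) | > 0 |
| disability weight | 0.010 (0.004) | ≥ 0 |
| baseline utility | 0.90 (0.120) | ≤ 1 |
| teeth per case | 1.64 (1.262) | ≥ 0 |
| check-up / restoration / travel | 54.69 (3.19) / 189.61 (17.95) / 12.34 (0.92) | ≥ 0 |

Effect-size SDs are not published (the original analyses generated the
distributions inside their modelling software without reporting them);
the preventive-fraction and odds-ratio SDs are backed out of
the cited meta-analyses' interval estimates, and the trial Δdmft values
use a ≈20% coefficient of variation.  These are package defaults, stated
here so they can be challenged.

Truncation is *naive* (parameters are the pre-truncation normal's):
with a large coefficient of variation this shifts realised means — e.g.
E[teeth/case] ≈ 1.88 > 1.64 and E[utility gain] ≈ 0.071 > 0.05 — so PSA
means sit systematically away from the deterministic run.  This is kept
deliberately: the published QALY-to-DALY ratio of the results table
(≈ 5.6–5.7) matches the truncation-shifted ratio of the two episode
values rather than the point-estimate ratio of exactly 5, indicating the
original analysis behaved the same way.  Degenerate distributions
(SD = 0) return the mean, and with all SDs zero the PSA collapses to the
deterministic run with zero standard errors — a tested invariant.

Summaries use ratio-of-means ICERs (standard cost-effectiveness analysis
practice, one ICER per arm) with explicit `dominant` / `dominated` /
`undefined` markers instead of exceptions; cost-effectiveness probability
is the share of iterations with `WTP × Δeffect − Δcost > 0`.  League
tables rank by AUD per DT prevented, ascending, dominant arms first.

## Numerical choices

* Schedules are tabulated at integer ages and linearly interpolated;
  requesting an age outside the tabulated range is an error, and config
  validation requires coverage of `[min start age, max start age +
  horizon]` up front.
* Adjusted incidence is floored at zero (dmft conversion) and preventive
  fractions/odds ratios are range-checked; a deciduous+permanent sum
  above 1 is rejected rather than silently renormalised.
* Truncation by resampling retries up to 10⁴ draws, then errors; no
  shipped distribution comes near that bound.
* Per-iteration seeds are derived as `(seed mod 65011 × 1009 + iteration
  × 7919) mod (2³¹ − 1)`, so a draw is fully determined by `(seed,
  iteration)` and independent of loop order; all generation runs under
  `withr::with_seed`, leaving the caller's RNG state untouched.
* Mass conservation holds to machine precision by construction (each
  outflow is a partition of the source state); the test suite asserts it
  at 10⁻⁹ against an independently coded loop reference.
* Monetary reporting rounds to millions with one decimal only in the
  formatted report; machine CSVs keep full precision.

## Known limitations

* dmft/DMFT increments are a proxy for caries incidence; converting a
  trial's cumulative dmft difference into per-cycle case probabilities
  via a teeth-per-case constant inherits that proxy status.
* The QALY instrument underlying the 0.05 utility gain is known to be
  insensitive to dental caries; QALY results are reported because health
  technology assessment processes require them, with DALYs alongside.
* One published cost cell (the varnish-with-screening first-year program
  cost) exceeds what the published fee schedule arithmetic yields
  ($34.6M vs $34.3M); the fixture stores the printed value as an
  annotation while the model uses the fee formula, and the anticipated
  visit count for anticipatory guidance follows the 11-visit reading
  (1 visit in year one, then 2/year), which the published cost schedule
  supports.
* Synthetic schedules are calibrated stand-ins (see above); absolute
  incremental quantities should not be quoted as estimates for the real
  population without substituting real incidence and mortality inputs.
* Travel costs for school-based programs are excluded (unknown per-child
  estimates), matching the source design; this understates those
  programs' costs.

## Problem sizes used in shipped results

The packaged acceptance computation runs 2,000 PSA iterations per
intervention on the full fixture cohorts; the test suite exercises the
same pipeline at 200 iterations (cost-effectiveness probabilities) and
500 iterations (ranking), sizes at which the Monte Carlo error is an
order of magnitude smaller than the smallest margin the assertions rely
on.
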