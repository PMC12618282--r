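Package: cariescea
Title: Cost-Effectiveness Modelling of Dental Caries Preventive
    Interventions in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-cohort Markov modelling and probabilistic
    cost-effectiveness analysis of preventive interventions for dental
    caries in children from low-income households: anticipatory guidance
    delivered by oral health therapists (home visits or telehealth),
    school-based fluoride varnish programs (dental or non-dental
    providers), and school-based fissure sealants.  Provides typed,
    validated parameter configurations with YAML round-trip, a synthetic
    epidemiology generator for age-specific caries incidence and
    background mortality schedules, a four-state cohort engine with
    half-cycle correction and discounting, intervention effect transforms
    (absolute dmft reduction, preventive fraction, odds ratio on occlusal
    molar surfaces), episode-based DALY/QALY valuation, Monte Carlo
    probabilistic sensitivity analysis with ICERs, dominance handling and
    cost-effectiveness probabilities at willingness-to-pay thresholds,
    and scenario orchestration with reproducible report files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
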