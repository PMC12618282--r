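# Synthetic age-specific caries incidence and background mortality
# schedules.  These stand in for national burden-of-disease and life-table
# extracts so every model stage is runnable and testable from code alone;
# the CSV interface lets real extracts be substituted.

#' Default age shape of per-person annual caries incidence
#'
#' A bimodal childhood profile: a flat early-childhood plateau while the
#' deciduous dentition is at risk, a trough around ages 6-7 as primary
#' teeth begin to exfoliate, a secondary peak near ages 8-10 as the newly
#' erupted first permanent molars accumulate caries, and low adolescent
#' rates thereafter.  The shape multiplies `base_rate`; at the default
#' base rate of 0.15/year it spans roughly 0.05-0.19/year across ages
#' 1-14 for the general population.  The default is calibrated once so
#' that prevented-case counts under the built-in cohorts land on the
#' order reported for the Australian low-income child population.
#'
#' @param age Numeric vector of ages in years.
#' @return Dimensionless multiplier, one per age.
#' @export
default_age_shape <- function(age) {
  0.34 + 0.36 / (1 + exp((age - 5.5) / 0.25)) +
    0.90 * exp(-(age - 9)^2 / (2 * 0.9^2))
}

#' Linear mixed-dentition eruption profile
#'
#' Share of incident caries arising in deciduous teeth: 1 up to age 5,
#' declining linearly to 0 at age 14 (the mixed-dentition window).
#'
#' @param age Numeric vector of ages in years.
#' @return Deciduous share in `[0, 1]`, one per age.
#' @export
deciduous_share_profile <- function(age) {
  pmin(1, pmax(0, (14 - age) / 9))
}

as_incidence_schedule <- function(tab, occlusal_molar_share = 0.5,
                                  params = NULL) {
  need <- c("age", "rate_general", "rate_low_income", "deciduous_share")
  chk(all(need %in% names(tab)), "incidence",
      paste("schedule needs columns:", paste(need, collapse = ", ")))
  chk(all(tab$rate_general >= 0 & tab$rate_general <= 1) &&
        all(tab$rate_low_income >= 0 & tab$rate_low_income <= 1),
      "incidence", "rates must be probabilities in [0, 1]")
  chk(all(tab$deciduous_share >= 0 & tab$deciduous_share <= 1),
      "incidence", "deciduous_share must be in [0, 1]")
  chk(is_prob(occlusal_molar_share), "occlusal_molar_share",
      "must be in [0, 1]")
  tab <- tab[order(tab$age), need, drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            occlusal_molar_share = occlusal_molar_share,
            params = params,
            class = c("incidence_schedule", "data.frame"))
}

#' Generate a synthetic caries incidence schedule
#'
#' Builds an age-indexed table of per-person annual probabilities of a new
#' dental caries case: `base_rate` times a smooth age curve times
#' multiplicative lognormal noise, clipped to `[0, 1]`.  The low-income
#' rate applies the higher caries prevalence among children from low
#' household income as a multiplicative ratio, capped at 1.  The schedule
#' also carries the deciduous/permanent split per age and the share of
#' permanent-teeth incidence attributable to occlusal surfaces of the
#' first/second permanent molars (the surfaces fissure sealants protect).
#'
#' Deterministic for a given seed: the same call reproduces the same
#' schedule bit for bit.
#'
#' @param seed Integer RNG seed.
#' @param ages Ages (years) to tabulate.
#' @param base_rate Reference per-person annual case probability.
#' @param low_income_ratio Multiplicative adjustment (>= 1) for the
#'   low-household-income population.
#' @param noise_sd Standard deviation of the lognormal age-level noise
#'   (0 gives the smooth curve exactly).
#' @param shape_fun Age-shape function multiplying `base_rate`.
#' @param eruption_fun Deciduous-share profile function of age.
#' @param occlusal_molar_share Proportion of permanent-teeth incidence on
#'   occlusal molar surfaces (default 0.5).
#' @return An `incidence_schedule` data frame with columns `age`,
#'   `rate_general`, `rate_low_income`, `deciduous_share`.
#' @export
#' @examples
#' sched <- make_incidence_schedule(seed = 1)
#' head(sched)
make_incidence_schedule <- function(seed = 1L,
                                    ages = 0:25,
                                    base_rate = 0.15,
                                    low_income_ratio = 1.5,
                                    noise_sd = 0.1,
                                    shape_fun = default_age_shape,
                                    eruption_fun = deciduous_share_profile,
                                    occlusal_molar_share = 0.5) {
  chk(is_prob(base_rate), "base_rate", "must be a probability in [0, 1]")
  chk(is_number(low_income_ratio) && low_income_ratio >= 1,
      "low_income_ratio", "must be >= 1")
  chk(is_number(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  ages <- sort(as.numeric(ages))

  noise <- withr::with_seed(as.integer(seed),
                            exp(rnorm(length(ages), 0, noise_sd)))
  general <- pmin(1, pmax(0, base_rate * shape_fun(ages) * noise))
  low_income <- pmin(1, general * low_income_ratio)
  if (all(general == 0) || all(general == 1)) {
    warning("degenerate incidence schedule: all rates are ",
            general[1L], call. = FALSE)
  }
  as_incidence_schedule(
    data.frame(age = ages,
               rate_general = general,
               rate_low_income = low_income,
               deciduous_share = eruption_fun(ages)),
    occlusal_molar_share = occlusal_molar_share,
    params = list(seed = as.integer(seed), base_rate = base_rate,
                  low_income_ratio = low_income_ratio, noise_sd = noise_sd))
}

schedule_lookup <- function(schedule, age, column) {
  rng <- range(schedule$age)
  if (any(age < rng[1L] | age > rng[2L])) {
    fail_field("age", sprintf("age %s outside schedule range [%g, %g]",
                              paste(age[age < rng[1L] | age > rng[2L]],
                                    collapse = ", "), rng[1L], rng[2L]))
  }
  approx(schedule$age, schedule[[column]], xout = age, rule = 1)$y
}

#' Split total caries incidence into deciduous and permanent components
#'
#' Evaluates the schedule at `age` (linear interpolation between tabulated
#' ages) and partitions the per-person annual rate by the mixed-dentition
#' eruption profile.  The two components always sum to the total rate.
#'
#' @param schedule An `incidence_schedule`.
#' @param age Age in years; must lie within the schedule's range.
#' @param population `"low_income"` (default) or `"general"`.
#' @return Named numeric `c(deciduous = , permanent = )`.
#' @export
#' @examples
#' sched <- make_incidence_schedule(seed = 1)
#' split_mixed_dentition(sched, 9.5)
split_mixed_dentition <- function(schedule, age,
                                  population = c("low_income", "general")) {
  population <- match.arg(population)
  col <- if (population == "low_income") "rate_low_income" else "rate_general"
  total <- schedule_lookup(schedule, age, col)
  share <- schedule_lookup(schedule, age, "deciduous_share")
  c(deciduous = total * share, permanent = total * (1 - share))
}

as_mortality_schedule <- function(tab, sex_mix_male = 0.512, params = NULL) {
  need <- c("age", "male", "female", "combined")
  chk(all(need %in% names(tab)), "mortality",
      paste("schedule needs columns:", paste(need, collapse = ", ")))
  for (col in c("male", "female", "combined")) {
    chk(all(tab[[col]] >= 0 & tab[[col]] <= 1), "mortality",
        sprintf("%s rates must be probabilities in [0, 1]", col))
  }
  chk(is_prob(sex_mix_male), "sex_mix_male", "must be in [0, 1]")
  tab <- tab[order(tab$age), need, drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            sex_mix_male = sex_mix_male,
            params = params,
            class = c("mortality_schedule", "data.frame"))
}

#' Generate a synthetic background mortality schedule
#'
#' Produces per-age, per-sex annual death probabilities with the U-shaped
#' child/adolescent profile of national life tables: elevated infant
#' mortality, a mid-childhood trough, and a rise through adolescence.  The
#' profile is scaled by `level` (so `level = 0` gives no deaths and
#' `level = 1` saturates at certain death within one cycle), with a fixed
#' male:female hazard ratio and a sex-mix-weighted combined rate.
#' Deterministic per seed.
#'
#' @param seed Integer RNG seed.
#' @param ages Ages (years) to tabulate.
#' @param level Overall mortality scale (annual probability at the profile
#'   floor); child cohorts are realistically around `3e-4`.
#' @param male_female_hazard_ratio Male:female mortality ratio.
#' @param sex_mix_male Male proportion of the cohort (0.512).
#' @param noise_sd Lognormal noise SD on the age profile.
#' @return A `mortality_schedule` data frame with columns `age`, `male`,
#'   `female`, `combined`.
#' @export
make_mortality_schedule <- function(seed = 1L,
                                    ages = 0:25,
                                    level = 3e-4,
                                    male_female_hazard_ratio = 1.3,
                                    sex_mix_male = 0.512,
                                    noise_sd = 0.05) {
  chk(is_prob(level), "level", "must be a probability in [0, 1]")
  chk(is_number(male_female_hazard_ratio) && male_female_hazard_ratio > 0,
      "male_female_hazard_ratio", "must be > 0")
  chk(is_prob(sex_mix_male), "sex_mix_male", "must be in [0, 1]")
  ages <- sort(as.numeric(ages))

  # U-shape with floor 1 so `level` is attained at the trough and level = 1
  # saturates every age at certain death.
  ushape <- 1 + 3 * exp(-ages / 1.2) + 0.8 * plogis((ages - 13) / 1.5)
  noise <- withr::with_seed(as.integer(seed),
                            exp(rnorm(length(ages), 0, noise_sd)))
  combined <- pmin(1, level * ushape * noise)
  hr <- male_female_hazard_ratio
  female <- pmin(1, combined / (sex_mix_male * hr + (1 - sex_mix_male)))
  male <- pmin(1, hr * female)
  as_mortality_schedule(
    data.frame(age = ages, male = male, female = female,
               combined = combined),
    sex_mix_male = sex_mix_male,
    params = list(seed = as.integer(seed), level = level,
                  male_female_hazard_ratio = hr, noise_sd = noise_sd))
}

# ---- CSV interchange -------------------------------------------------------

#' Write / read schedules as CSV
#'
#' Plain-text interchange so externally sourced rates (e.g. national
#' burden-of-disease extracts) can replace the synthetic generator.  The
#' incidence layout is one row per age with columns `age`, `sex` (always
#' `"all"`; incidence is not sex-differentiated), `rate_general`,
#' `rate_low_income`, `deciduous_share`, `occlusal_molar_share`.  The
#' mortality layout is long: columns `age`, `sex` (`"male"`/`"female"`),
#' `rate`.
#'
#' @param schedule The schedule object to write.
#' @param path CSV file path.
#' @param sex_mix_male Male cohort proportion used to recombine the sexes
#'   when reading mortality.
#' @return The file path (writers) or the schedule object (readers).
#' @name schedule_csv
NULL

#' @rdname schedule_csv
#' @export
write_incidence_csv <- function(schedule, path) {
  chk(inherits(schedule, "incidence_schedule"), "schedule",
      "must be an incidence_schedule")
  out <- data.frame(age = schedule$age, sex = "all",
                    rate_general = schedule$rate_general,
                    rate_low_income = schedule$rate_low_income,
                    deciduous_share = schedule$deciduous_share,
                    occlusal_molar_share = attr(schedule,
                                                "occlusal_molar_share"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname schedule_csv
#' @export
read_incidence_csv <- function(path) {
  chk(file.exists(path), "path", sprintf("file not found: %s", path))
  tab <- read.csv(path)
  as_incidence_schedule(tab,
                        occlusal_molar_share = tab$occlusal_molar_share[1L])
}

#' @rdname schedule_csv
#' @export
write_mortality_csv <- function(schedule, path) {
  chk(inherits(schedule, "mortality_schedule"), "schedule",
      "must be a mortality_schedule")
  out <- rbind(
    data.frame(age = schedule$age, sex = "male", rate = schedule$male),
    data.frame(age = schedule$age, sex = "female", rate = schedule$female))
  write.csv(out[order(out$age, out$sex), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname schedule_csv
#' @export
read_mortality_csv <- function(path, sex_mix_male = 0.512) {
  chk(file.exists(path), "path", sprintf("file not found: %s", path))
  tab <- read.csv(path)
  male <- tab[tab$sex == "male", ]
  female <- tab[tab$sex == "female", ]
  chk(nrow(male) > 0 && nrow(female) > 0, "path",
      "mortality CSV needs male and female rows")
  male <- male[order(male$age), ]
  female <- female[order(female$age), ]
  chk(identical(male$age, female$age), "path",
      "male and female rows must tabulate the same ages")
  combined <- sex_mix_male * male$rate + (1 - sex_mix_male) * female$rate
  as_mortality_schedule(
    data.frame(age = male$age, male = male$rate, female = female$rate,
               combined = pmin(1, combined)),
    sex_mix_male = sex_mix_male)
}
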