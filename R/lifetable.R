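# Cause-deleted life table: apportion national AAA deaths (ICD-10 I71) to
# deprivation quintiles by population share, delete them from all-cause
# deaths, and convert central rates to within-year death probabilities.

#' Synthetic mortality inputs
#'
#' Generates a toy national mortality data set emulating what the national
#' statistics tables provide: all-cause and AAA (ICD-10 I71) death counts by
#' single year of age and sex, plus population counts by age, sex and IMD
#' quintile.  All-cause mortality follows a Gompertz curve; quintile
#' populations are given a deprivation gradient in both size-at-age (more
#' deprived areas have younger age structures) and underlying mortality used
#' to generate the national death counts.  AAA deaths are a small,
#' age-peaked, male-dominated fraction of all deaths.
#'
#' @param ages single years of age covered (default 65:109).
#' @param sexes character vector; the simulation consumes `"male"` only but
#'   both sexes are supported for completeness.
#' @param base_population population per age-65 quintile cell.
#' @param m65 male all-cause central mortality rate at 65 (Q3 level).
#' @param gompertz_b log-rate increase per year of age.
#' @param quintile_gradient relative mortality by quintile Q1..Q5 used when
#'   generating the national death counts.
#' @param aaa_share share of male deaths at the AAA peak (around age 80)
#'   attributed to AAA.
#' @return an object of class `mortality_inputs`: a list of two data frames,
#'   `deaths` (age, sex, all_cause, aaa) and `population` (age, sex,
#'   quintile, population).
#' @export
synth_mortality_inputs <- function(ages = 65:109,
                                   sexes = c("male", "female"),
                                   base_population = 50000,
                                   m65 = 0.012,
                                   gompertz_b = 0.095,
                                   quintile_gradient = c(1.30, 1.15, 1.00, 0.88, 0.78),
                                   aaa_share = 0.005) {
  if (length(quintile_gradient) != 5) {
    stop_validation("quintile_gradient must have length 5")
  }
  check_nonnegative(c(base_population, m65, gompertz_b, aaa_share), "mortality inputs")

  pop <- expand.grid(age = ages, sex = sexes, quintile = QUINTILES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qi <- match(pop$quintile, QUINTILES)
  sex_mult <- ifelse(pop$sex == "male", 1, 0.72)
  grad <- quintile_gradient[qi]
  # survivorship from the quintile-specific Gompertz hazard shapes the
  # age structure: more deprived quintiles thin out faster with age
  cum_haz <- (m65 * grad * sex_mult / gompertz_b) *
    (exp(gompertz_b * (pop$age - ages[1])) - 1)
  pop$population <- base_population * exp(-cum_haz)

  true_m <- m65 * grad * sex_mult * exp(gompertz_b * (pop$age - ages[1]))
  pop$.deaths <- pop$population * pmin(true_m, 1)

  deaths <- stats::aggregate(.deaths ~ age + sex, data = pop, FUN = sum)
  names(deaths)[names(deaths) == ".deaths"] <- "all_cause"
  # AAA deaths: age-peaked (around 80), male-dominated
  peak <- exp(-((deaths$age - 80) / 12)^2)
  aaa_mult <- ifelse(deaths$sex == "male", 1, 0.25)
  deaths$aaa <- deaths$all_cause * aaa_share * peak * aaa_mult
  pop$.deaths <- NULL

  structure(list(deaths = deaths, population = pop),
            class = "mortality_inputs")
}

#' Construct mortality inputs from data frames
#'
#' Validates and assembles a `mortality_inputs` object from user-supplied
#' tables, e.g. read from delimited text.
#'
#' @param deaths data frame with columns `age`, `sex`, `all_cause`, `aaa`.
#' @param population data frame with columns `age`, `sex`, `quintile`,
#'   `population`.
#' @return a `mortality_inputs` object.
#' @export
mortality_inputs <- function(deaths, population) {
  need_d <- c("age", "sex", "all_cause", "aaa")
  need_p <- c("age", "sex", "quintile", "population")
  if (!all(need_d %in% names(deaths))) {
    stop_load("deaths table needs columns: ", paste(need_d, collapse = ", "))
  }
  if (!all(need_p %in% names(population))) {
    stop_load("population table needs columns: ", paste(need_p, collapse = ", "))
  }
  if (any(deaths$aaa > deaths$all_cause + 1e-9)) {
    stop_validation("AAA deaths exceed all-cause deaths in some age-sex stratum")
  }
  check_nonnegative(deaths$all_cause, "all-cause deaths")
  check_nonnegative(deaths$aaa, "AAA deaths")
  check_nonnegative(population$population, "population")
  structure(list(deaths = deaths, population = population),
            class = "mortality_inputs")
}

#' Apportion national AAA deaths to deprivation quintiles
#'
#' Allocates the national AAA death count of each age-sex stratum to IMD
#' quintiles in proportion to each quintile's share of that stratum's
#' population.  Counts are real-valued (no rounding), so per stratum the
#' quintile counts sum exactly to the national count.
#'
#' @param inputs a `mortality_inputs` object.
#' @return data frame with columns `age`, `sex`, `quintile`, `aaa_deaths`,
#'   `all_cause_deaths` (both apportioned), `population`, `pop_share`.
#' @export
apportion_aaa_deaths <- function(inputs) {
  stopifnot(inherits(inputs, "mortality_inputs"))
  pop <- inputs$population
  totals <- stats::aggregate(population ~ age + sex, data = pop, FUN = sum)
  names(totals)[names(totals) == "population"] <- ".total"
  m <- merge(pop, totals, by = c("age", "sex"))
  m <- merge(m, inputs$deaths, by = c("age", "sex"))
  bad <- m$.total <= 0 & m$all_cause > 0
  if (any(bad)) {
    stop_validation("zero total population in stratum with nonzero deaths (age ",
                    m$age[bad][1], ", ", m$sex[bad][1], ")")
  }
  m$pop_share <- ifelse(m$.total > 0, m$population / m$.total, 0)
  m$aaa_deaths <- m$pop_share * m$aaa
  m$all_cause_deaths <- m$pop_share * m$all_cause
  out <- m[order(m$sex, m$age, m$quintile),
           c("age", "sex", "quintile", "aaa_deaths", "all_cause_deaths",
             "population", "pop_share")]
  rownames(out) <- NULL
  out
}

#' Non-AAA mortality table
#'
#' Derives the cause-deleted (non-AAA) mortality table by age and quintile:
#' the central rate `m = (apportioned all-cause deaths - apportioned AAA
#' deaths) / population`, and the within-year death probability under the
#' uniform-deaths assumption used in national life tables,
#' `q = m / (1 + 0.5 m)`.
#'
#' @param inputs a `mortality_inputs` object.
#' @param sex which sex's table to return (default `"male"`, the screened
#'   cohort).
#' @return an object of class `nonaaa_mortality`: a data frame with columns
#'   `age`, `quintile`, `m` (deaths per person-year) and `q` (probability).
#' @export
non_aaa_mortality <- function(inputs, sex = "male") {
  app <- apportion_aaa_deaths(inputs)
  app <- app[app$sex == sex, ]
  if (nrow(app) == 0) stop_validation("no rows for sex '", sex, "'")
  non_aaa <- app$all_cause_deaths - app$aaa_deaths
  if (any(non_aaa < -1e-9)) {
    stop_validation("negative non-AAA deaths after apportionment (age ",
                    app$age[non_aaa < -1e-9][1], ")")
  }
  m <- ifelse(app$population > 0, pmax(non_aaa, 0) / app$population, 0)
  out <- data.frame(age = app$age, quintile = app$quintile,
                    m = m, q = m_to_q(m))
  out <- out[order(out$quintile, out$age), ]
  rownames(out) <- NULL
  structure(out, class = c("nonaaa_mortality", "data.frame"))
}

#' Impose a deprivation gradient on a non-AAA mortality table
#'
#' Scales each quintile's central rates by a multiplier and recomputes the
#' death probabilities.  Under the population-share apportionment contract
#' the derived rates are identical across quintiles whenever death counts
#' are only available nationally; this helper lets the simulator carry a
#' deprivation mortality gradient anyway.
#'
#' @param table a `nonaaa_mortality` table.
#' @param multipliers length-5 positive rate multipliers for Q1..Q5.
#' @return a `nonaaa_mortality` table.
#' @export
apply_rate_gradient <- function(table, multipliers) {
  stopifnot(inherits(table, "nonaaa_mortality"))
  if (length(multipliers) != 5 || any(multipliers <= 0)) {
    stop_validation("multipliers must be 5 positive values")
  }
  table$m <- table$m * multipliers[match(table$quintile, QUINTILES)]
  table$q <- m_to_q(table$m)
  table
}

# Central rate to within-year death probability under uniform deaths,
# q = m / (1 + 0.5 m); the map stays below 1 only for m <= 2, so it is
# capped at certain death for extreme rates.
m_to_q <- function(m) {
  pmin(m / (1 + 0.5 * m), 1)
}

# Cumulative distribution of non-AAA death time (years since age 65) for one
# quintile, on a single-year grid with certain death at the age cap.
death_time_cdf <- function(table, quintile, entry_age = 65, age_cap = 110) {
  rows <- table[table$quintile == quintile & table$age >= entry_age &
                  table$age < age_cap, ]
  rows <- rows[order(rows$age), ]
  if (nrow(rows) == 0) stop_validation("mortality table has no rows for ", quintile)
  surv <- cumprod(1 - rows$q)
  list(ages = rows$age, q = rows$q,
       F = 1 - surv,                       # P(death within k+1 years)
       t_cap = age_cap - entry_age)
}

#' Sample non-AAA death times
#'
#' Inverse-CDF draw of death time (years since age 65) from a
#' `nonaaa_mortality` table, uniform within the year of death, with certain
#' death at the age cap.  Supplying the uniforms makes the draw
#' deterministic, which the paired simulation relies on.
#'
#' @param table a `nonaaa_mortality` table.
#' @param quintile `"Q1"`..`"Q5"`.
#' @param u uniforms in (0, 1), one per individual.
#' @param entry_age,age_cap entry age and certain-death cap.
#' @return death times in years since entry, in `(0, age_cap - entry_age]`.
#' @export
sample_death_times <- function(table, quintile, u, entry_age = 65, age_cap = 110) {
  cdf <- death_time_cdf(table, quintile, entry_age, age_cap)
  Fk <- c(0, cdf$F)                     # F at start of year k (k = 0, 1, ...)
  k <- findInterval(u, Fk, rightmost.closed = FALSE) - 1L
  n_years <- length(cdf$F)
  t <- numeric(length(u))
  beyond <- k >= n_years | u >= cdf$F[n_years]
  kk <- pmin(k, n_years - 1L)
  width <- Fk[kk + 2L] - Fk[kk + 1L]
  frac <- ifelse(width > 0, (u - Fk[kk + 1L]) / width, 0.5)
  t <- kk + pmin(pmax(frac, 0), 1)
  t[beyond] <- cdf$t_cap
  pmin(t, cdf$t_cap)
}
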