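# Synthetic age-by-quintile health-related quality of life surface.

#' Synthetic HRQoL surface
#'
#' Utility weights by single year of age (65 to `age_cap`) and IMD quintile,
#' standing in for the external survey-based age/sex/IMD-adjusted HRQoL
#' source.  Construction is linear in age — `utility(age) = u65 - decline *
#' (age - 65)` — clipped to `[0, 1]`.  The invitation to screen itself never
#' alters utility: QALY differences between arms arise only through
#' survival.
#'
#' @param u65 length-5 utility at age 65 per quintile Q1..Q5 (default a
#'   mild deprivation gradient, 0.78 to 0.84).
#' @param decline utility lost per year of age (default 0.004/yr); must be
#'   nonnegative.
#' @param age_cap last age carried (default 110).
#' @return an object of class `hrqol_surface`: a matrix with one row per
#'   age 65..`age_cap` and one column per quintile.
#' @export
synth_hrqol_surface <- function(u65 = c(0.78, 0.80, 0.82, 0.83, 0.84),
                                decline = 0.004,
                                age_cap = 110) {
  if (length(u65) != 5) stop_validation("u65 must have length 5")
  check_probability(u65, "u65")
  if (!is.finite(decline) || decline < 0) {
    stop_validation("decline must be nonnegative; got ", decline)
  }
  ages <- 65:age_cap
  m <- vapply(u65, function(u) pmin(pmax(u - decline * (ages - 65), 0), 1),
              numeric(length(ages)))
  dimnames(m) <- list(age = ages, quintile = QUINTILES)
  structure(m, class = c("hrqol_surface", "matrix"))
}

#' Utility weight lookup
#'
#' Utility at an exact (possibly fractional) age, piecewise constant over
#' single years of age; ages beyond the surface cap take the last value.
#'
#' @param surface an `hrqol_surface`.
#' @param age age in years.
#' @param quintile `"Q1"`..`"Q5"`.
#' @return numeric utility weights.
#' @export
utility_at <- function(surface, age, quintile) {
  stopifnot(inherits(surface, "hrqol_surface"))
  ages <- as.integer(rownames(surface))
  idx <- pmin(pmax(floor(age), ages[1]), ages[length(ages)]) - ages[1] + 1L
  surface[idx, quintile]
}
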