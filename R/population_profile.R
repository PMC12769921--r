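# Per-quintile population profile: counts, screening eligibility shares,
# opportunity-cost shares, and baseline quality-adjusted life expectancy.

#' Per-quintile population profile
#'
#' Houses the distributional inputs of the DCEA: the total English
#' population `N`, quintile populations `n_i` (equal fifths by
#' construction of IMD quintiles), the fraction of each quintile that is
#' male, aged 65, and hence eligible for screening (`rho_t`), each
#' quintile's share of the marginal product of NHS expenditure (`rho_k`,
#' the distribution of health opportunity cost), and baseline
#' quality-adjusted life expectancy at birth (`qale`, the with-policy
#' distribution).
#'
#' Defaults: 280,000 eligible 65-year-old men split 17/19/21/22/22% across
#' Q1..Q5 (as published); opportunity-cost shares implied by the published
#' per-quintile opportunity-cost column, 350:291:288:212:185 renormalised
#' (Q1 26.4%, Q5 14.0%, matching the reported 26%/14% extremes); QALE
#' anchored at 63 years for Q1 — the only published quintile — with a
#' synthetic linear gradient to 73 years for Q5, consistent with the
#' roughly 10-year longevity gap between the most and least affluent areas.
#'
#' @param total_population total population `N` sharing the health
#'   opportunity cost (default 56.5 million).
#' @param eligible_total number of 65-year-old men eligible for screening.
#' @param eligible_shares length-5 fractions of eligible men per quintile;
#'   must sum to 1 within 0.02 (then normalised).
#' @param hoc_shares length-5 shares of marginal health expenditure product;
#'   must sum to 1 within 0.02 (then normalised).
#' @param qale length-5 baseline QALE at birth in years, Q1..Q5.
#' @return an object of class `population_profile`: a list with `N`, and
#'   per-quintile vectors `n`, `eligible_n`, `rho_t`, `rho_k`, `qale`.
#' @export
population_profile <- function(total_population = 56.5e6,
                               eligible_total = 280000,
                               eligible_shares = c(0.17, 0.19, 0.21, 0.22, 0.22),
                               hoc_shares = c(350, 291, 288, 212, 185) / 1326,
                               qale = c(63, 65.5, 68, 70.5, 73)) {
  if (length(eligible_shares) != 5 || length(hoc_shares) != 5 || length(qale) != 5) {
    stop_validation("eligible_shares, hoc_shares and qale must have length 5")
  }
  check_nonnegative(total_population, "total_population")
  check_nonnegative(eligible_total, "eligible_total")
  check_nonnegative(hoc_shares, "hoc_shares")
  for (v in list(eligible_shares, hoc_shares)) {
    if (abs(sum(v) - 1) > 0.02) {
      stop_validation("shares must sum to 1 within 0.02 before normalisation; got ",
                      signif(sum(v), 5))
    }
  }
  check_probability(eligible_shares, "eligible_shares")
  if (any(qale <= 0)) stop_validation("baseline QALE must be positive")

  eligible_shares <- eligible_shares / sum(eligible_shares)
  hoc_shares <- hoc_shares / sum(hoc_shares)
  n <- rep(total_population / 5, 5)
  eligible_n <- eligible_total * eligible_shares

  structure(
    list(N = total_population,
         n = stats::setNames(n, QUINTILES),
         eligible_n = stats::setNames(eligible_n, QUINTILES),
         rho_t = stats::setNames(eligible_n / n, QUINTILES),
         rho_k = stats::setNames(hoc_shares, QUINTILES),
         qale = stats::setNames(qale, QUINTILES)),
    class = "population_profile"
  )
}

#' @export
print.population_profile <- function(x, ...) {
  cat("Population profile (N =", format(x$N, big.mark = ","), ")\n")
  print(data.frame(n = x$n, eligible_n = round(x$eligible_n),
                   rho_t = signif(x$rho_t, 4), rho_k = round(x$rho_k, 4),
                   qale = x$qale))
  invisible(x)
}
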