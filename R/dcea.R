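# Distributional cost-effectiveness analysis: health opportunity cost and
# its socioeconomic distribution, per-quintile net health benefit,
# counterfactual QALE, Atkinson equally-distributed-equivalent health,
# threshold inequality aversion, and scenarios.

#' Assemble DCEA inputs
#'
#' Combines a [population_profile()] with the simulated (or hand-entered)
#' per-quintile incremental costs and QALYs of invitation versus no
#' invitation.  Supply either per-eligible-person increments (`inc_cost`,
#' `inc_qaly`) or population totals (`total_cost`, `total_qaly`); totals
#' take precedence.  `hoc_i` optionally fixes the per-quintile opportunity
#' cost directly (e.g. a published column); otherwise the total opportunity
#' cost is split by the profile's `rho_k` shares.
#'
#' @param profile a `population_profile`.
#' @param inc_cost,inc_qaly length-5 per-person increments (GBP, QALYs).
#' @param total_cost,total_qaly length-5 population totals.
#' @param k marginal productivity of health expenditure, GBP per QALY
#'   (default 13,000): each GBP 13,000 of cost displaces one QALY elsewhere.
#' @param epsilon Atkinson inequality aversion (default 3.5, the
#'   income-related estimate for England).
#' @param hoc_i optional length-5 per-quintile opportunity cost in QALYs.
#' @return an object of class `dcea_inputs`.
#' @export
dcea_inputs <- function(profile, inc_cost = NULL, inc_qaly = NULL,
                        total_cost = NULL, total_qaly = NULL,
                        k = 13000, epsilon = 3.5, hoc_i = NULL) {
  stopifnot(inherits(profile, "population_profile"))
  if (!is.finite(k) || k <= 0) stop_validation("k must be positive")
  if (!is.finite(epsilon) || epsilon < 0) stop_validation("epsilon must be >= 0")
  if (is.null(total_cost)) {
    if (is.null(inc_cost)) stop_validation("supply inc_cost or total_cost")
    total_cost <- inc_cost * profile$eligible_n
  }
  if (is.null(total_qaly)) {
    if (is.null(inc_qaly)) stop_validation("supply inc_qaly or total_qaly")
    total_qaly <- inc_qaly * profile$eligible_n
  }
  if (length(total_cost) != 5 || length(total_qaly) != 5) {
    stop_validation("per-quintile inputs must have length 5")
  }
  if (!is.null(hoc_i) && length(hoc_i) != 5) {
    stop_validation("hoc_i must have length 5")
  }
  structure(
    list(profile = profile,
         total_cost = stats::setNames(as.numeric(total_cost), QUINTILES),
         total_qaly = stats::setNames(as.numeric(total_qaly), QUINTILES),
         k = k, epsilon = epsilon,
         hoc_i = if (is.null(hoc_i)) NULL else stats::setNames(as.numeric(hoc_i), QUINTILES)),
    class = "dcea_inputs"
  )
}

#' Health opportunity cost
#'
#' Total QALYs forgone elsewhere in the health system when the programme's
#' incremental costs displace other expenditure: the sum of per-quintile
#' total incremental costs divided by the marginal productivity `k`
#' (1 QALY per GBP `k`).  The total is distributed across quintiles by the
#' profile's opportunity-cost shares `rho_k` (or taken from `hoc_i` when
#' the inputs fix it).
#'
#' @param inputs a [dcea_inputs()] object.
#' @return list with `total` (QALYs) and `per_quintile` (length-5 QALYs).
#' @export
health_opportunity_cost <- function(inputs) {
  stopifnot(inherits(inputs, "dcea_inputs"))
  total <- sum(inputs$total_cost) / inputs$k
  per_q <- if (!is.null(inputs$hoc_i)) inputs$hoc_i else inputs$profile$rho_k * total
  list(total = total, per_quintile = per_q)
}

#' Net health benefit per quintile
#'
#' Per-person net health benefit in each quintile: QALYs gained by the
#' quintile's eligible men minus the quintile's share of the health
#' opportunity cost, spread over the quintile's whole population
#' `nhb_i = (total_qaly_i - HOC_i) / n_i`.
#'
#' The total net population health is always the identity
#' `sum(total_qaly) - HOC_total`.  When the inputs fix the per-quintile
#' allocation through `hoc_i`, that allocation is taken at face value for
#' the quintile-level nets, so (e.g. with an independently rounded
#' published column) their sum may differ from the total by the rounding
#' in the supplied allocation.
#'
#' @param inputs a [dcea_inputs()] object.
#' @param hoc output of [health_opportunity_cost()] (computed if missing).
#' @return list with `nhb` (per person, length 5), `population` (QALYs per
#'   quintile, `nhb * n`), and `total` (net population health, QALYs).
#' @export
net_health_benefit <- function(inputs, hoc = health_opportunity_cost(inputs)) {
  n <- inputs$profile$n
  if (any(n <= 0)) stop_validation("quintile populations must be positive")
  pop_net <- inputs$total_qaly - hoc$per_quintile
  list(nhb = pop_net / n, population = pop_net,
       total = sum(inputs$total_qaly) - hoc$total)
}

#' Counterfactual QALE without the policy
#'
#' The population distribution of quality-adjusted life expectancy that
#' would be expected without the screening programme: the with-policy QALE
#' minus the per-person net health benefit, `h0_i = h1_i - nhb_i`.  A
#' quintile with negative net benefit therefore has *higher* QALE without
#' the policy.
#'
#' @param profile a `population_profile` (its `qale` is the with-policy
#'   distribution).
#' @param nhb length-5 per-person net health benefit.
#' @return length-5 QALE without the policy.
#' @export
counterfactual_qale <- function(profile, nhb) {
  stopifnot(inherits(profile, "population_profile"))
  profile$qale - nhb
}

#' Atkinson equally-distributed-equivalent health
#'
#' The uniform health level society with inequality aversion `epsilon`
#' values equally to the actual distribution `h` with subgroup sizes `n`:
#' per person, `EDE = [(1/N) sum n_i h_i^(1-eps)]^(1/(1-eps))` for
#' `eps != 1`, with the geometric-mean limit at `eps = 1` and the
#' population-weighted mean at `eps = 0`.  The Atkinson index is
#' `1 - EDE / mean(h)`.
#'
#' @param h per-subgroup health (positive).
#' @param n subgroup sizes.
#' @param epsilon inequality aversion, `>= 0`.
#' @return list with `ede` (per person), `h_ede` (`N * ede`), and
#'   `atkinson_index`.
#' @export
atkinson_ede <- function(h, n, epsilon) {
  if (length(h) != length(n)) stop_validation("h and n must have equal length")
  if (!is.finite(epsilon) || epsilon < 0) stop_validation("epsilon must be >= 0")
  if (any(h <= 0)) {
    stop_validation("all health levels must be positive for the Atkinson EDE")
  }
  check_nonnegative(n, "subgroup sizes")
  N <- sum(n)
  w <- n / N
  mu <- sum(w * h)
  ede <- if (abs(epsilon - 1) < 1e-9) {
    exp(sum(w * log(h)))
  } else {
    e <- 1 - epsilon
    # compute on the log scale relative to the mean for numerical stability
    # at large epsilon
    mu * sum(w * (h / mu)^e)^(1 / e)
  }
  list(ede = ede, h_ede = N * ede, atkinson_index = 1 - ede / mu)
}

#' EDE change and inequality decomposition
#'
#' The social value of the policy is the change in population EDE health,
#' `dEDE = H_EDE(with) - H_EDE(without)`.  Subtracting the total net
#' population health isolates the part attributable to the change in
#' inequality alone: `inequality_value = dEDE - sum(nhb_i * n_i)`.  The
#' pair `(inequality_value, net population health)` is the policy's point
#' on the equity-efficiency impact plane.
#'
#' @param h1,h0 per-quintile QALE with and without the policy.
#' @param n quintile populations.
#' @param epsilon inequality aversion (one value for both states).
#' @param net_total total net population health `sum(nhb_i * n_i)`
#'   (computed from `h1 - h0` if missing).
#' @return list with `delta_ede`, `inequality_value`, `net_total`,
#'   `equity_point`.
#' @export
ede_change_and_decomposition <- function(h1, h0, n, epsilon,
                                         net_total = sum((h1 - h0) * n)) {
  with_p <- atkinson_ede(h1, n, epsilon)
  without_p <- atkinson_ede(h0, n, epsilon)
  delta <- with_p$h_ede - without_p$h_ede
  list(delta_ede = delta,
       inequality_value = delta - net_total,
       net_total = net_total,
       equity_point = c(inequality = delta - net_total, efficiency = net_total))
}

#' Threshold inequality aversion
#'
#' The inequality aversion at which the policy and its absence are valued
#' equally: the root of `dEDE(eps) = H_EDE(h1; eps) - H_EDE(h0; eps) = 0`.
#' The curve is evaluated on a grid over `range` (default 0 to 20, step
#' 0.1); each sign change is bracketed and bisected to `tol`, and the
#' smallest root is reported.  Returns `NA` for the root when `dEDE` never
#' changes sign on the range (e.g. when every quintile gains).
#'
#' @param h1,h0,n as for [ede_change_and_decomposition()].
#' @param range length-2 epsilon range, `0 <= lo < hi`.
#' @param step grid step for the reported curve.
#' @param tol bisection tolerance (default 1e-4).
#' @return list with `epsilon_star` (or `NA`), `curve` (data frame
#'   `epsilon`, `delta_ede`), and `brackets` (all sign-change intervals).
#' @export
threshold_epsilon <- function(h1, h0, n, range = c(0, 20), step = 0.1,
                              tol = 1e-4) {
  if (length(range) != 2 || !all(is.finite(range)) || range[1] < 0 ||
      range[2] <= range[1]) {
    stop_validation("range must be a valid [lo, hi] with 0 <= lo < hi")
  }
  f <- function(eps) {
    atkinson_ede(h1, n, eps)$h_ede - atkinson_ede(h0, n, eps)$h_ede
  }
  grid <- seq(range[1], range[2], by = step)
  if (grid[length(grid)] < range[2]) grid <- c(grid, range[2])
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  change <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  brackets <- lapply(change, function(i) c(grid[i], grid[i + 1]))
  exact <- grid[vals == 0 & grid > range[1]]

  root <- NA_real_
  roots <- numeric(0)
  for (b in brackets) {
    lo <- b[1]; hi <- b[2]
    flo <- f(lo)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(c(roots, exact))
  if (length(roots)) root <- roots[1]

  list(epsilon_star = root,
       curve = data.frame(epsilon = grid, delta_ede = vals),
       brackets = brackets)
}

#' Run the full DCEA
#'
#' Chains opportunity cost, net health benefit, counterfactual QALE, the
#' Atkinson EDE with and without the policy, the inequality decomposition,
#' and the threshold inequality aversion into one result object.
#'
#' @param inputs a [dcea_inputs()] object.
#' @param scenario label stored with the result.
#' @param epsilon_range range for the threshold search and EDE curve.
#' @return an object of class `dcea_result`; see the fields in the
#'   implementation or `print()` it.
#' @export
dcea <- function(inputs, scenario = "base", epsilon_range = c(0, 20)) {
  stopifnot(inherits(inputs, "dcea_inputs"))
  profile <- inputs$profile
  hoc <- health_opportunity_cost(inputs)
  nhb <- net_health_benefit(inputs, hoc)
  h1 <- profile$qale
  h0 <- counterfactual_qale(profile, nhb$nhb)
  eps <- inputs$epsilon

  with_p <- atkinson_ede(h1, profile$n, eps)
  without_p <- atkinson_ede(h0, profile$n, eps)
  decomp <- ede_change_and_decomposition(h1, h0, profile$n, eps,
                                         net_total = nhb$total)
  thr <- threshold_epsilon(h1, h0, profile$n, range = epsilon_range)

  structure(
    list(scenario = scenario,
         inputs = inputs,
         hoc_total = hoc$total,
         hoc_per_quintile = hoc$per_quintile,
         nhb = nhb$nhb,
         population_net = nhb$population,
         net_population_health = nhb$total,
         total_qalys = sum(inputs$total_qaly),
         h1 = h1, h0 = h0,
         qale_gap_with = unname(h1[5] - h1[1]),
         qale_gap_without = unname(h0[5] - h0[1]),
         ede_with = with_p, ede_without = without_p,
         atkinson_index = with_p$atkinson_index,
         delta_ede = decomp$delta_ede,
         inequality_value = decomp$inequality_value,
         equity_point = decomp$equity_point,
         epsilon = eps,
         threshold = thr),
    class = "dcea_result"
  )
}

#' Scenario analyses
#'
#' * `"equal_hoc"` — reallocates the health opportunity cost equally across
#'   quintiles (`rho_k = 0.2` for all) and recomputes the DCEA without
#'   resimulation; the total opportunity cost is unchanged.
#' * `"leveling_up"` — reruns the cohort simulation with every
#'   best-case-flagged access/uptake/delivery parameter copied to all
#'   quintiles ([leveling_up_params()]); eligibility and costs untouched.
#'   Requires `sim_bundle`.
#'
#' @param base a [dcea_inputs()] object (the base case).
#' @param scenario `"equal_hoc"` or `"leveling_up"`.
#' @param sim_bundle for `"leveling_up"`: a list with `params`, `costs`,
#'   `hrqol`, `diameters`, `mortality`, `n` (cohort size per quintile),
#'   `seed`, and optionally `config`.
#' @return a [dcea()] result flagged with the scenario name.
#' @export
run_scenario <- function(base, scenario, sim_bundle = NULL) {
  stopifnot(inherits(base, "dcea_inputs"))
  if (scenario == "equal_hoc") {
    profile <- base$profile
    profile$rho_k <- stats::setNames(rep(0.2, 5), QUINTILES)
    inputs <- dcea_inputs(profile,
                          total_cost = base$total_cost,
                          total_qaly = base$total_qaly,
                          k = base$k, epsilon = base$epsilon, hoc_i = NULL)
    return(dcea(inputs, scenario = "equal_hoc"))
  }
  if (scenario == "leveling_up") {
    if (is.null(sim_bundle)) {
      stop_validation("leveling_up requires a sim_bundle (params, costs, hrqol, diameters, mortality, n, seed)")
    }
    params_up <- leveling_up_params(sim_bundle$params)
    cfg <- sim_bundle$config %||% sim_config()
    aggs <- lapply(QUINTILES, function(q) {
      run_cohort(q, sim_bundle$n, sim_bundle$seed, params_up,
                 sim_bundle$costs, sim_bundle$hrqol, sim_bundle$diameters,
                 sim_bundle$mortality, cfg)
    })
    inputs <- dcea_inputs(base$profile,
                          inc_cost = vapply(aggs, `[[`, numeric(1), "mean_inc_cost"),
                          inc_qaly = vapply(aggs, `[[`, numeric(1), "mean_inc_qaly"),
                          k = base$k, epsilon = base$epsilon)
    res <- dcea(inputs, scenario = "leveling_up")
    res$aggregates <- aggs
    return(res)
  }
  stop_validation("unknown scenario '", scenario,
                  "' (equal_hoc or leveling_up)")
}

#' @export
print.dcea_result <- function(x, ...) {
  cat("DCEA result — scenario:", x$scenario, "\n")
  cat(sprintf("  health opportunity cost: %.1f QALYs\n", x$hoc_total))
  cat(sprintf("  total QALYs generated:  %.1f\n", x$total_qalys))
  cat(sprintf("  net population health:  %.1f QALYs\n", x$net_population_health))
  tab <- data.frame(hoc = round(x$hoc_per_quintile, 1),
                    net = round(x$population_net, 1),
                    h_with = round(x$h1, 4), h_without = round(x$h0, 4))
  print(tab)
  cat(sprintf("  Atkinson index (eps = %.2f): %.3e\n", x$epsilon,
              x$atkinson_index))
  cat(sprintf("  dEDE: %.2f QALYs; inequality value: %.2f QALYs\n",
              x$delta_ede, x$inequality_value))
  if (is.na(x$threshold$epsilon_star)) {
    cat("  no threshold inequality aversion on the searched range\n")
  } else {
    cat(sprintf("  threshold inequality aversion: %.3f\n",
                x$threshold$epsilon_star))
  }
  invisible(x)
}
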