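# Distributional analysis: opportunity cost, net health benefit,
# counterfactual QALE, Atkinson EDE, threshold aversion, scenarios.

profile <- population_profile()
ref <- load_quintile_aggregates()

test_that("health opportunity cost divides total cost by the marginal productivity", {
  inp <- dcea_inputs(profile, total_cost = ref$total_cost,
                     total_qaly = ref$total_qalys)
  hoc <- health_opportunity_cost(inp)
  expect_equal(hoc$total, sum(ref$total_cost) / 13000, tolerance = 1e-12)
  expect_equal(round(hoc$total), 1325)
  expect_equal(sum(hoc$per_quintile), hoc$total, tolerance = 1e-9)

  zero <- dcea_inputs(profile, total_cost = rep(0, 5), total_qaly = rep(0, 5))
  hz <- health_opportunity_cost(zero)
  expect_equal(hz$total, 0)
  expect_equal(unname(hz$per_quintile), rep(0, 5))

  prof_eq <- population_profile(hoc_shares = rep(0.2, 5))
  inp_eq <- dcea_inputs(prof_eq, total_cost = ref$total_cost,
                        total_qaly = ref$total_qalys)
  expect_equal(unname(health_opportunity_cost(inp_eq)$per_quintile),
               rep(sum(ref$total_cost) / 13000 / 5, 5))
  expect_error(dcea_inputs(profile, total_cost = ref$total_cost,
                           total_qaly = ref$total_qalys, k = -1), "positive")
})

test_that("opportunity cost is linear in costs", {
  for (c_mult in c(0.5, 2, 10)) {
    a <- health_opportunity_cost(dcea_inputs(profile,
                                             total_cost = ref$total_cost,
                                             total_qaly = ref$total_qalys))
    b <- health_opportunity_cost(dcea_inputs(profile,
                                             total_cost = c_mult * ref$total_cost,
                                             total_qaly = ref$total_qalys))
    expect_equal(b$total, c_mult * a$total, tolerance = 1e-12)
    expect_equal(b$per_quintile, c_mult * a$per_quintile, tolerance = 1e-12)
  }
})

test_that("published totals reproduce the net health impact column", {
  inp <- dcea_inputs(profile, total_cost = ref$total_cost,
                     total_qaly = ref$total_qalys, hoc_i = ref$hoc)
  nhb <- net_health_benefit(inp)
  expect_equal(unname(nhb$population[["Q1"]]), -106)
  expect_equal(unname(nhb$population[["Q5"]]), 185)
  expect_equal(unname(nhb$population[["Q4"]]), 120, tolerance = 1)
  expect_equal(nhb$total, 1642 - sum(ref$total_cost) / 13000, tolerance = 1e-9)
  expect_equal(round(nhb$total), 317)

  zero <- dcea_inputs(profile, total_cost = rep(0, 5), total_qaly = rep(0, 5))
  expect_equal(unname(net_health_benefit(zero)$nhb), rep(0, 5))
})

test_that("counterfactual QALE subtracts per-person net benefit with the right sign", {
  expect_equal(counterfactual_qale(profile, rep(0, 5)), profile$qale)
  h0 <- counterfactual_qale(profile, c(-1e-4, 0, 0, 0, 0))
  expect_equal(unname(h0[["Q1"]]), 63.0001)
  # algebraic identity: population QALE change equals net population health
  inp <- dcea_inputs(profile, total_cost = ref$total_cost,
                     total_qaly = ref$total_qalys)
  nhb <- net_health_benefit(inp)
  h0 <- counterfactual_qale(profile, nhb$nhb)
  expect_equal(sum(profile$n * (profile$qale - h0)), nhb$total,
               tolerance = 1e-9)
})

test_that("Atkinson EDE matches the closed form, its limits, and its bounds", {
  # perfect equality: EDE = h and index = 0 at any aversion
  for (eps in c(0, 0.5, 1, 3.5, 20)) {
    r <- atkinson_ede(rep(50, 5), rep(10, 5), eps)
    expect_equal(r$ede, 50, tolerance = 1e-12)
    expect_equal(r$atkinson_index, 0, tolerance = 1e-12)
  }
  # eps = 0: population-weighted mean
  r0 <- atkinson_ede(c(40, 60), c(3, 1), 0)
  expect_equal(r0$ede, (3 * 40 + 60) / 4, tolerance = 1e-12)
  # two-group reference point, eps = 3.5, against the independent oracle
  r <- atkinson_ede(c(40, 60), c(1, 1), 3.5)
  expect_equal(r$ede, oracle_ede(c(40, 60), c(1, 1), 3.5), tolerance = 1e-6)
  expect_equal(r$ede, 46.63, tolerance = 0.005)
  expect_lt(r$ede, 50)
  expect_equal(r$h_ede, 2 * r$ede, tolerance = 1e-9)
  # index bounds and monotonicity of EDE in aversion
  h <- profile$qale; n <- profile$n
  edes <- vapply(seq(0, 20, by = 0.5),
                 function(e) atkinson_ede(h, n, e)$ede, numeric(1))
  expect_true(all(diff(edes) <= 1e-9))
  idx <- vapply(seq(0, 20, by = 0.5),
                function(e) atkinson_ede(h, n, e)$atkinson_index, numeric(1))
  expect_true(all(idx >= 0 & idx < 1))
  # continuity at eps = 1
  e1 <- atkinson_ede(h, n, 1)$ede
  expect_lt(abs(atkinson_ede(h, n, 1 + 1e-6)$ede - e1), 1e-4)
  expect_lt(abs(atkinson_ede(h, n, 1 - 1e-6)$ede - e1), 1e-4)
  expect_error(atkinson_ede(c(-1, 60), c(1, 1), 2), "positive")
})

test_that("the EDE decomposition vanishes when it must and signs losses correctly", {
  n <- c(2, 1)
  h1 <- c(60, 70); h0 <- c(60.4, 69.5)
  # eps = 0: EDE reduces to the mean, inequality value is exactly zero
  d0 <- ede_change_and_decomposition(h1, h0, n, 0)
  expect_equal(d0$inequality_value, 0, tolerance = 1e-9)
  # distribution-neutral change on an equal baseline: no inequality value
  dn <- ede_change_and_decomposition(c(50.1, 50.1), c(50, 50), c(1, 1), 3.5)
  expect_equal(dn$inequality_value, 0, tolerance = 1e-9)
  # losses concentrated on the worse-off group: negative inequality value
  dl <- ede_change_and_decomposition(c(59.5, 70.5), c(60, 70), c(1, 1), 3.5)
  expect_lt(dl$inequality_value, 0)
})

test_that("threshold aversion matches a fine grid-search oracle", {
  n <- c(1, 1)
  h1 <- c(60, 70)
  h0 <- c(60.5, 69.3)  # policy harms the worse-off, helps the better-off
  thr <- threshold_epsilon(h1, h0, n)
  expect_false(is.na(thr$epsilon_star))
  # independent oracle: 1e-3-step scan of the direct closed form
  grid <- seq(0, 20, by = 1e-3)
  dd <- vapply(grid, function(e) {
    2 * (oracle_ede(h1, n, e) - oracle_ede(h0, n, e))
  }, numeric(1))
  flip <- which(sign(dd[-1]) * sign(dd[-length(dd)]) < 0)[1]
  expect_lt(abs(thr$epsilon_star - grid[flip]), 1e-3 + 1e-9)
  # curve starts at the net population health (eps = 0 identity)
  expect_equal(thr$curve$delta_ede[1], sum((h1 - h0) * n), tolerance = 1e-9)
  # all-gain policies have no threshold
  none <- threshold_epsilon(c(61, 71), c(60, 70), n)
  expect_true(is.na(none$epsilon_star))
  expect_error(threshold_epsilon(h1, h0, n, range = c(5, 2)), "range")
})

test_that("equal-opportunity-cost scenario reallocates but conserves the total", {
  inp <- dcea_inputs(profile, total_cost = ref$total_cost,
                     total_qaly = ref$total_qalys, hoc_i = ref$hoc)
  base <- dcea(inp)
  sc <- run_scenario(inp, "equal_hoc")
  expect_equal(sc$hoc_total, base$hoc_total, tolerance = 1e-12)
  expect_equal(unname(sc$hoc_per_quintile), rep(base$hoc_total / 5, 5))
  expect_equal(unname(sc$population_net[["Q1"]]), -21, tolerance = 0.01)
  expect_error(run_scenario(inp, "flatten"), "unknown scenario")
  expect_error(run_scenario(inp, "leveling_up"), "sim_bundle")
})

test_that("leveling-up copies every best-case parameter to all quintiles", {
  up <- leveling_up_params(default_params)
  expect_equal(up$probs$p_attend, rep(0.8342, 5))
  expect_equal(up$probs$p_dropout, rep(0.0381, 5))
  expect_equal(up$probs$p_nonvisualised, rep(0.0090, 5))
  expect_equal(up$probs$wait_consult, rep(0.0413, 5))
  expect_equal(up$probs$wait_surgery, rep(0.2847, 5))
  expect_equal(unname(up$logit_elective_open[, "intercept"]), rep(7.09, 5))
  expect_equal(unname(up$logit_emergency_open[, "age"]), rep(-0.004, 5))
  # unflagged rows untouched
  expect_equal(up$probs$p_reinvite, default_params$probs$p_reinvite)
  expect_equal(up$mortality_logits, default_params$mortality_logits)
})

test_that("full DCEA satisfies the accounting identity and reports a threshold", {
  inp <- dcea_inputs(profile, total_cost = ref$total_cost,
                     total_qaly = ref$total_qalys)
  res <- dcea(inp)
  expect_equal(res$net_population_health,
               sum(inp$total_qaly) - res$hoc_total, tolerance = 1e-9)
  expect_equal(sum(res$inputs$profile$n * (res$h1 - res$h0)),
               res$net_population_health, tolerance = 1e-6)
  expect_true(res$atkinson_index >= 0 && res$atkinson_index < 1)
  # losses concentrated on Q1 drive a sign change within the default range
  expect_false(is.na(res$threshold$epsilon_star))
  expect_lt(res$inequality_value, 0)
  expect_gt(res$net_population_health, 0)
})
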