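# Paired discrete event simulation.

cfg_default <- sim_config()
hrqol_flat <- synth_hrqol_surface(u65 = rep(1, 5), decline = 0)
hrqol_grad <- synth_hrqol_surface()
mort_tab <- sim_mortality()

test_that("one undiseased life-year at utility 1 yields the closed-form discounted QALY", {
  ind <- make_individual("Q3", d0 = 2.0, growth = 0, death_time = 1, seed = 7)
  po <- simulate_pair(ind, default_params, default_costs, hrqol_flat)
  oracle <- (1 - 1.035^-1) / log(1.035)
  expect_equal(po$uninvited$qalys, oracle, tolerance = 1e-6)
  expect_equal(po$invited$qalys, oracle, tolerance = 1e-6)
  expect_equal(po$inc_qaly, 0)
})

test_that("with attendance off and incidental detection off, screening only costs letters", {
  p0 <- default_params
  p0$probs$p_attend <- rep(0, 5)
  cfg <- sim_config(incidental_hazard = 0)
  for (s in c(2, 9, 23)) {
    ind <- make_individual("Q2", d0 = 3.8, growth = 0.02, death_time = 22, seed = s)
    po <- simulate_pair(ind, p0, default_costs, hrqol_grad, cfg)
    expect_equal(po$inc_qaly, 0)
    letters <- 2.13 * (1 + (ind$draws$u_reinvite < p0$probs$p_reinvite[2]))
    expect_equal(po$inc_cost, letters)
  }
})

test_that("a small-aorta attender is screened once and discharged", {
  # baseline 2.0 cm, zero growth: one screen then discharge; no QALY change
  found <- FALSE
  for (s in 1:50) {
    ind <- make_individual("Q4", d0 = 2.0, growth = 0, death_time = 18, seed = s)
    dr <- ind$draws
    if (dr$u_attend < default_params$probs$p_attend[4] &&
        dr$u_nonvis >= default_params$probs$p_nonvisualised[4] &&
        dr$u_reinvite >= default_params$probs$p_reinvite[4]) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
  po <- simulate_pair(ind, default_params, default_costs, hrqol_grad)
  expect_equal(po$inc_cost, 2.13 + 40.43)   # letter + screening scan at t = 0
  expect_equal(po$inc_qaly, 0)
  expect_equal(po$invited$counts[["screen_detected"]], 0L)
})

test_that("the uninvited arm is invariant to every screening parameter", {
  p_alt <- default_params
  p_alt$probs$p_attend <- rep(0.999, 5)
  p_alt$probs$p_reinvite <- rep(0, 5)
  p_alt$probs$p_nonvisualised <- rep(0.5, 5)
  p_alt$probs$p_dropout <- rep(0.9, 5)
  p_alt$probs$wait_consult <- rep(1.5, 5)
  p_alt$probs$wait_surgery <- rep(2.5, 5)
  for (s in 1:40) {
    ind <- make_individual("Q1", d0 = 3.2 + 0.1 * (s %% 5),
                           growth = 0.01 * (s %% 4), death_time = 5 + s %% 30,
                           seed = s)
    a <- simulate_pair(ind, default_params, default_costs, hrqol_grad)$uninvited
    b <- simulate_pair(ind, p_alt, default_costs, hrqol_grad)$uninvited
    expect_identical(a$events, b$events)
    expect_identical(a$cost, b$cost)
    expect_identical(a$qalys, b$qalys)
  }
})

test_that("each arm dies exactly once, in order, with nonnegative outcomes", {
  for (s in 1:30) {
    ind <- make_individual("Q3", d0 = 2.5 + 0.15 * (s %% 12),
                           growth = 0.005 * (s %% 8), death_time = 2 + s,
                           seed = 100 + s)
    po <- simulate_pair(ind, default_params, default_costs, hrqol_grad)
    for (arm in list(po$invited, po$uninvited)) {
      deaths <- grepl("death", arm$events$event)
      expect_equal(sum(deaths), 1L)
      expect_true(all(diff(arm$events$time) >= 0))      # time-ordered log
      expect_identical(arm$events$time[deaths], arm$death_time)
      expect_gte(arm$cost, 0)
      expect_gte(arm$qalys, 0)
      expect_lte(arm$death_time, 45)
    }
  }
})

test_that("discounted QALYs never exceed undiscounted QALYs or the horizon", {
  cfg0 <- sim_config(discount_rate = 0)
  for (s in c(3, 14, 27)) {
    ind <- make_individual("Q5", d0 = 3.5, growth = 0.02, death_time = 35,
                           seed = s)
    disc <- simulate_pair(ind, default_params, default_costs, hrqol_grad,
                          cfg_default)
    undisc <- simulate_pair(ind, default_params, default_costs, hrqol_grad,
                            cfg0)
    expect_lte(disc$invited$qalys, undisc$invited$qalys)
    expect_lte(undisc$invited$qalys, 45)
  }
})

test_that("cohorts are bit-identical under the same seed and conserve deaths", {
  dm <- synth_diameter_model(seed = 8)
  a <- run_cohort("Q2", 2000, 77, default_params, default_costs, hrqol_grad,
                  dm, mort_tab)
  b <- run_cohort("Q2", 2000, 77, default_params, default_costs, hrqol_grad,
                  dm, mort_tab)
  expect_identical(a, b)
  expect_error(run_cohort("Q2", 0, 1, default_params, default_costs,
                          hrqol_grad, dm, mort_tab), ">= 1")
  # every simulated man dies exactly once per arm: AAA deaths cannot exceed n
  expect_true(all(a$counts$aaa_deaths <= a$n))
  expect_true(all(a$counts[, -1] >= 0))
})

test_that("raising attendance does not decrease screen detections (common seeds)", {
  dm <- synth_diameter_model(seed = 8)
  p_hi <- default_params
  p_hi$probs$p_attend <- pmin(default_params$probs$p_attend + 0.15, 1)
  lo <- run_cohort("Q1", 4000, 5, default_params, default_costs, hrqol_grad,
                   dm, mort_tab)
  hi <- run_cohort("Q1", 4000, 5, p_hi, default_costs, hrqol_grad,
                   dm, mort_tab)
  n_det <- function(agg) agg$counts$screen_detected[agg$counts$arm == "invited"]
  expect_gte(n_det(hi), n_det(lo))
  # and the uninvited arm aggregates are untouched
  expect_identical(lo$mean_qaly_uninvited, hi$mean_qaly_uninvited)
  expect_identical(lo$mean_cost_uninvited, hi$mean_cost_uninvited)
})

test_that("with AAA disabled, cohort QALYs match the life-table expectation", {
  dm0 <- synth_diameter_model(prevalence_q5 = 0, growth_mean = 0,
                              growth_sd = 0, seed = 13)
  cfg <- sim_config(rupture_alpha = -Inf, incidental_hazard = 0)
  agg <- run_cohort("Q3", 20000, 19, default_params, default_costs,
                    hrqol_grad, dm0, mort_tab, cfg)
  # closed-form expectation by inverse-CDF quadrature over the death-time
  # distribution, using the independent discounted-QALY oracle
  m <- 2e5
  u <- (seq_len(m) - 0.5) / m
  t <- sample_death_times(mort_tab, "Q3", u)
  expected <- mean(oracle_qalys(t, "Q3", hrqol_grad))
  expect_lt(abs(agg$mean_qaly_uninvited - expected), 3 * agg$se_qaly_uninvited)
  expect_equal(agg$mean_inc_qaly, 0)
})

test_that("higher rupture hazard lowers QALYs in both arms but screening still helps", {
  dm <- synth_diameter_model(seed = 16)
  base_cfg <- sim_config()
  hot_cfg <- sim_config(rupture_alpha = -16)   # ~ e-fold higher hazard
  gains <- numeric(0)
  for (s in 1:10) {
    base <- run_cohort("Q1", 3000, s, default_params, default_costs,
                       hrqol_grad, dm, mort_tab, base_cfg)
    hot <- run_cohort("Q1", 3000, s, default_params, default_costs,
                      hrqol_grad, dm, mort_tab, hot_cfg)
    expect_lte(hot$mean_qaly_uninvited, base$mean_qaly_uninvited)
    gains <- c(gains, hot$mean_inc_qaly)
  }
  expect_gte(mean(gains), 0)   # invited-minus-uninvited gain stays nonnegative
})
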