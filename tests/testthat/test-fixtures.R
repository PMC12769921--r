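test_that("pathway parameter table loads with published values and best-case flags", {
  p <- default_params
  expect_equal(p$probs$p_attend, c(0.6736, 0.7403, 0.7895, 0.8157, 0.8342))
  expect_equal(p$probs$p_reinvite[1], 0.3609)
  expect_equal(p$probs$wait_surgery[3], 0.2847)
  expect_equal(unname(p$best_case[["p_dropout"]]), "Q3")
  expect_equal(p$probs$p_dropout[3], 0.0381)
  expect_equal(unname(p$best_case[["p_attend"]]), "Q5")
  expect_true(is.na(p$best_case[["p_reinvite"]]))
  expect_equal(unname(p$logit_elective_open["Q1", ]),
               c(5.53, -0.11, 0.03))
  expect_equal(unname(p$mortality_logits$emergency_open),
               c(-17.68, 0.18))
})

test_that("pathway loader rejects malformed tables", {
  tab <- read.csv(pathway_params_file())
  tmp <- withr::local_tempfile(fileext = ".csv")

  bad <- tab[tab$item != "p_attend", ]
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_pathway_params(tmp), "p_attend")

  bad <- tab
  bad$Q2[bad$item == "p_attend"] <- 1.2
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_pathway_params(tmp), "\\[0, 1\\]")

  bad <- tab[, setdiff(names(tab), "Q4")]
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_pathway_params(tmp), "Q4")
})

test_that("pathway parameters round-trip through delimited text", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pathway_params(default_params, tmp)
  reread <- load_pathway_params(tmp)
  expect_equal(reread, default_params)
})

test_that("cost schedule loads the 16 published items and round-trips", {
  co <- default_costs
  expect_length(co, 16)
  expect_equal(co[["invitation"]], 2.13)
  expect_equal(co[["elective_evar"]], 15645.68)
  expect_equal(co[["emergency_open"]], 22608.57)
  expect_equal(co[["surveillance_post_open"]], 211.02)

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cost_schedule(co, tmp)
  expect_equal(load_cost_schedule(tmp), co)
})

test_that("cost loader names missing rows and rejects negative costs", {
  tab <- read.csv(cost_schedule_file())
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[tab$item != "surveillance_scan", ], tmp, row.names = FALSE)
  expect_error(load_cost_schedule(tmp), "surveillance_scan")
  bad <- tab
  bad$cost[1] <- -5
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_cost_schedule(tmp), "negative")
})

test_that("population profile defaults match the published distributional anchors", {
  prof <- population_profile()
  expect_equal(unname(prof$rho_k[["Q1"]]), 350 / 1326, tolerance = 1e-12)
  expect_equal(unname(prof$rho_k[["Q1"]]), 0.264, tolerance = 0.005)
  expect_equal(unname(prof$rho_k[["Q5"]]), 0.140, tolerance = 0.005)
  expect_equal(sum(prof$rho_k), 1, tolerance = 1e-12)
  expect_equal(unname(prof$qale[["Q1"]]), 63)
  expect_equal(sum(prof$n), prof$N)
  expect_equal(unname(prof$eligible_n / sum(prof$eligible_n)),
               c(0.17, 0.19, 0.21, 0.22, 0.22) / 1.01, tolerance = 1e-12)
  expect_true(all(prof$rho_t >= 0 & prof$rho_t <= 1))
})

test_that("population profile normalises and validates shares", {
  prof <- population_profile(eligible_shares = rep(0.2, 5))
  expect_equal(unname(prof$eligible_n), rep(56000, 5))
  expect_error(population_profile(eligible_shares = c(0.4, 0.2, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(population_profile(qale = c(-1, 65, 68, 70, 73)), "positive")
})

test_that("diameter model reproduces the configured deprivation gradient", {
  dm <- synth_diameter_model(seed = 21)
  expect_true(all(diff(dm$prevalence) <= 0))  # nonincreasing Q1 -> Q5
  n <- 1e5
  d1 <- sample_baseline_diameters(dm, "Q1", n)
  d5 <- sample_baseline_diameters(dm, "Q5", n)
  p1 <- mean(d1 >= 3.0)
  p5 <- mean(d5 >= 3.0)
  # 3 Monte-Carlo SEs on the ratio via the delta method
  se_ratio <- (p1 / p5) * sqrt((1 - p1) / (n * p1) + (1 - p5) / (n * p5))
  expect_lt(abs(p1 / p5 - 2.0), 3 * se_ratio + 1e-12)
  expect_lt(abs(p1 / p5 - 2.0), 0.2 * 2.0)   # within 10% of the target ratio
})

test_that("zero prevalence yields no aneurysmal baselines; seeds reproduce", {
  dm0 <- synth_diameter_model(prevalence_q5 = 0, seed = 4)
  d <- sample_baseline_diameters(dm0, "Q1", 5e4)
  expect_true(all(d < 3.0))
  dm <- synth_diameter_model(seed = 9)
  expect_identical(sample_baseline_diameters(dm, "Q3", 1000),
                   sample_baseline_diameters(dm, "Q3", 1000))
  expect_error(synth_diameter_model(ratio_q1_q5 = 0.5), ">= 1")
  expect_error(synth_diameter_model(prevalence_q5 = 1.2), "\\[0, 1\\)")
})

test_that("HRQoL surface is linear, clipped, ordered, and validated", {
  s <- synth_hrqol_surface(u65 = rep(0.8, 5), decline = 0.004)
  expect_equal(unname(utility_at(s, 75, "Q1")), 0.76)
  s1 <- synth_hrqol_surface(u65 = rep(1, 5), decline = 0)
  expect_true(all(s1 == 1))
  grad <- synth_hrqol_surface()  # Q1 lower than Q5 by default
  expect_true(all(grad[, "Q1"] <= grad[, "Q5"]))
  expect_true(all(grad >= 0 & grad <= 1))
  expect_true(all(apply(grad, 2, function(col) all(diff(col) <= 0))))
  expect_error(synth_hrqol_surface(decline = -0.01), "nonnegative")
})
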