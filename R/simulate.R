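# Paired discrete event simulation of invited vs uninvited lifetimes.
#
# Each simulated man owns one set of natural-history draws (baseline
# diameter, growth rate, rupture-time exponential, non-AAA death time) and
# one set of pathway decision draws (attendance, dropout stream, repair
# choice, operative death, ...).  Both arms consume the same draws, so the
# arms differ only through what screening detects — the paired
# counterfactual / common-random-numbers design.

#' Simulation configuration
#'
#' Collects every tunable the event simulation uses, with the package
#' defaults.  Rupture hazard and incidental-detection defaults are
#' uncalibrated synthetic values (see the methods vignette).
#'
#' @param discount_rate annual discount rate for costs and QALYs,
#'   continuous-time (default 0.035).
#' @param age_cap certain-death age (default 110).
#' @param rupture_alpha,rupture_beta rupture hazard
#'   `lambda(t) = exp(alpha + beta * diameter_cm)`.
#' @param incidental_hazard constant hazard (per year) of incidental AAA
#'   detection once the diameter exceeds 3.0 cm, applied identically in both
#'   arms and to surveillance dropouts.
#' @param p_emergency_operated probability a rupture reaches emergency
#'   surgery; otherwise immediate AAA death.
#' @param p_turndown probability of turn-down at elective consultation,
#'   leading to annual post-turn-down surveillance.
#' @param p_reintervention one-off reintervention probability after any
#'   repair, uniform over `reintervention_window` years.
#' @param reintervention_window years over which reintervention may occur.
#' @param surv_interval_small,surv_interval_large surveillance scan
#'   intervals (years) for diameters 3.0-4.4 cm and 4.5-5.4 cm.
#' @param large_threshold,referral_threshold,detection_threshold diameter
#'   cut points in cm (4.5, 5.5, 3.0).
#' @param operative_death_delay years from repair to a 30-day operative
#'   death (30/365.25).
#' @param incidental_wait_consult,incidental_wait_surgery,incidental_dropout
#'   referral-pathway frictions applied after *incidental* detection.  These
#'   are deliberately configuration constants rather than the per-quintile
#'   screening-programme values, so the uninvited arm is invariant to every
#'   screening parameter.
#' @param max_surveillance_scans length of the per-individual dropout
#'   uniform stream.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(discount_rate = 0.035,
                       age_cap = 110,
                       rupture_alpha = -17,
                       rupture_beta = 2.5,
                       incidental_hazard = 0.01,
                       p_emergency_operated = 0.35,
                       p_turndown = 0.10,
                       p_reintervention = 0.08,
                       reintervention_window = 5,
                       surv_interval_small = 1,
                       surv_interval_large = 0.25,
                       large_threshold = 4.5,
                       referral_threshold = 5.5,
                       detection_threshold = 3.0,
                       operative_death_delay = 30 / 365.25,
                       incidental_wait_consult = 0.05,
                       incidental_wait_surgery = 0.31,
                       incidental_dropout = 0,
                       max_surveillance_scans = 200L) {
  check_probability(c(p_emergency_operated, p_turndown, p_reintervention,
                      incidental_dropout),
                    "pathway probabilities")
  check_nonnegative(c(discount_rate, incidental_hazard, reintervention_window,
                      surv_interval_small, surv_interval_large,
                      incidental_wait_consult, incidental_wait_surgery),
                    "sim_config values")
  structure(as.list(environment()), class = "sim_config")
}

# Per-individual pathway decision draws; one named stream per decision so
# arms and scenarios share them.  The dropout stream is generated lazily
# from child_seed(seed, 11).
individual_draws <- function(seed) {
  set.seed(seed)
  list(seed = seed,
       u_attend = stats::runif(1),
       u_reinvite = stats::runif(1),
       u_nonvis = stats::runif(1),
       u_turndown = stats::runif(1),
       u_reach = stats::runif(1),
       u_repair_elective = c(choice = stats::runif(1), death = stats::runif(1)),
       u_repair_emergency = c(choice = stats::runif(1), death = stats::runif(1)),
       u_reint = stats::runif(1),
       u_reint_t = stats::runif(1),
       e_incid = stats::rexp(8))
}

#' Construct a simulated individual
#'
#' One 65-year-old man: quintile, baseline aortic diameter, individual
#' annual growth rate, non-AAA death time, rupture-time exponential draw,
#' and the seed of his pathway decision streams.  The same individual
#' drives both the invited and the uninvited arm of [simulate_pair()].
#'
#' @param quintile `"Q1"`..`"Q5"`.
#' @param d0 baseline diameter in cm (> 0).
#' @param growth annual exponential growth rate.
#' @param death_time non-AAA death time in years since entry (> 0).
#' @param seed integer; seeds the pathway decision draws.
#' @param e_rupture optional unit-exponential rupture draw (drawn from
#'   `seed` if missing).
#' @return an object of class `aaa_individual`.
#' @export
make_individual <- function(quintile, d0, growth, death_time, seed = 1L,
                            e_rupture = NULL) {
  quintile <- match.arg(quintile, QUINTILES)
  if (!is.finite(d0) || d0 <= 0) stop_validation("baseline diameter must be positive")
  if (!is.finite(death_time) || death_time <= 0) {
    stop_validation("non-AAA death time must be positive")
  }
  if (is.null(e_rupture)) {
    set.seed(child_seed(seed, 5L))
    e_rupture <- stats::rexp(1)
  }
  structure(
    list(quintile = quintile, d0 = d0, growth = growth,
         t_death = death_time, e_rupture = e_rupture,
         seed = as.integer(seed),
         draws = individual_draws(child_seed(seed, 0L))),
    class = "aaa_individual"
  )
}

# Vectorised discounted-QALY function for one quintile: utility piecewise
# constant over single years of age, continuous discounting.
make_qaly_fn <- function(hrqol, quintile, rate, age_cap = 110) {
  u <- as.numeric(utility_at(hrqol, 65:(age_cap - 1), quintile))
  K <- length(u)
  di <- discount_integral(0:(K - 1), 1:K, rate)
  Qcum <- c(0, cumsum(u * di))
  function(T) {
    T <- pmin(pmax(T, 0), K)
    k <- pmin(floor(T), K - 1)
    Qcum[k + 1] + u[k + 1] * discount_integral(k, T, rate)
  }
}

# --- single-arm walk -------------------------------------------------------

# nat: list(d0, growth, t_end, t_rup, quintile)   (t_end = capped death time)
# q:   list of quintile pathway values (p_dropout, wait_consult, wait_surgery)
# Returns cost/qaly (discounted), death time/cause, event log, counts.
walk_arm <- function(nat, draws, q, params, costs, cfg, qaly_fn,
                     screen_detected) {
  ev_t <- numeric(0); ev_e <- character(0); ev_c <- numeric(0)
  add <- function(t, e, c = 0) {
    ev_t[[length(ev_t) + 1L]] <<- t
    ev_e[[length(ev_e) + 1L]] <<- e
    ev_c[[length(ev_c) + 1L]] <<- c
  }
  counts <- c(surveilled = 0L, referred = 0L, elective_repairs = 0L,
              emergency_repairs = 0L, ruptures = 0L, aaa_deaths = 0L)
  t_end <- nat$t_end
  t_rup <- nat$t_rup          # natural rupture time; cancelled by repair
  death <- list(time = t_end, cause = "non_aaa")

  u_drop <- NULL
  drop_idx <- 0L
  next_drop <- function() {
    if (is.null(u_drop)) {
      set.seed(child_seed(draws$seed, 11L))
      u_drop <<- stats::runif(cfg$max_surveillance_scans)
    }
    drop_idx <<- drop_idx + 1L
    if (drop_idx > length(u_drop)) 1 else u_drop[drop_idx]
  }
  incid_idx <- 0L
  next_incid <- function() {
    incid_idx <<- incid_idx + 1L
    if (incid_idx > length(draws$e_incid)) Inf else draws$e_incid[incid_idx]
  }

  post_repair <- function(t0, type, setting) {
    if (draws$u_reint < cfg$p_reintervention) {
      t_ri <- t0 + draws$u_reint_t * cfg$reintervention_window
      if (t_ri < t_end) {
        add(t_ri, paste0("reintervention_", setting, "_", type),
            costs[[paste("reintervention", setting, type, sep = "_")]])
      }
    }
    if (type == "evar") {
      k <- 1
      while (t0 + k < t_end) {
        add(t0 + k, "post_evar_surveillance", costs[["surveillance_post_evar"]])
        k <- k + 1
      }
    } else if (t0 + 1 < t_end) {
      add(t0 + 1, "post_open_surveillance", costs[["surveillance_post_open"]])
    }
  }

  do_repair <- function(t0, setting) {
    aorta_mm <- 10 * nat$d0 * exp(nat$growth * t0)
    u <- if (setting == "elective") draws$u_repair_elective else draws$u_repair_emergency
    res <- repair_choice_and_mortality(nat$quintile, setting, 65 + t0,
                                       aorta_mm, params, u = u)
    add(t0, paste(setting, res$type, "repair", sep = "_"),
        costs[[paste(setting, res$type, sep = "_")]])
    if (setting == "elective") {
      counts[["elective_repairs"]] <<- counts[["elective_repairs"]] + 1L
    } else {
      counts[["emergency_repairs"]] <<- counts[["emergency_repairs"]] + 1L
    }
    t_rup <<- Inf                       # repair removes rupture risk
    if (res$died) {
      t_od <- t0 + cfg$operative_death_delay
      if (t_od < t_end) death <<- list(time = t_od, cause = "aaa")
      # else the non-AAA death supervenes first
    } else {
      post_repair(t0, res$type, setting)
    }
  }

  rupture <- function(t0) {
    counts[["ruptures"]] <<- counts[["ruptures"]] + 1L
    add(t0, "rupture", 0)
    if (draws$u_reach < cfg$p_emergency_operated) {
      do_repair(t0, "emergency")
    } else {
      death <<- list(time = t0, cause = "aaa")
    }
  }

  turndown_surveillance <- function(t0) {
    k <- 1
    repeat {
      tk <- t0 + k
      if (t_rup < tk && t_rup < t_end) { rupture(t_rup); return(invisible()) }
      if (tk >= t_end) return(invisible())
      add(tk, "turndown_surveillance", costs[["surveillance_scan_turndown"]])
      k <- k + 1
    }
  }

  referral <- function(t0, programme) {
    counts[["referred"]] <<- counts[["referred"]] + 1L
    wait_c <- if (programme) q$wait_consult else cfg$incidental_wait_consult
    wait_s <- if (programme) q$wait_surgery else cfg$incidental_wait_surgery
    t_c <- t0 + wait_c
    if (t_rup < t_c && t_rup < t_end) { rupture(t_rup); return(invisible()) }
    if (t_c >= t_end) return(invisible())
    add(t_c, "consultation", costs[["consultation"]])
    if (draws$u_turndown < cfg$p_turndown) {
      turndown_surveillance(t_c)
      return(invisible())
    }
    t_s <- t_c + wait_s
    if (t_rup < t_s && t_rup < t_end) { rupture(t_rup); return(invisible()) }
    if (t_s >= t_end) return(invisible())
    do_repair(t_s, "elective")
  }

  surveillance <- function(t0, programme) {
    counts[["surveilled"]] <<- counts[["surveilled"]] + 1L
    add(t0, if (programme) "surveillance_entry" else "incidental_detection", 0)
    p_drop <- if (programme) q$p_dropout else cfg$incidental_dropout
    t <- t0
    repeat {
      d_now <- nat$d0 * exp(nat$growth * t)
      if (d_now >= cfg$referral_threshold) { referral(t, programme); return(invisible()) }
      if (d_now < cfg$detection_threshold) { undetected(t); return(invisible()) }
      interval <- if (d_now < cfg$large_threshold) cfg$surv_interval_small else cfg$surv_interval_large
      t_next <- t + interval
      if (t_rup < t_next && t_rup < t_end) { rupture(t_rup); return(invisible()) }
      if (t_next >= t_end) return(invisible())
      if (next_drop() < p_drop) {        # dropped out before this scan
        add(t_next, "surveillance_dropout", 0)
        undetected(t_next)
        return(invisible())
      }
      add(t_next, "surveillance_scan", costs[["surveillance_scan"]])
      t <- t_next
    }
  }

  # Undetected with (possibly) an AAA: waits for incidental detection once
  # the diameter exceeds 3.0 cm, or rupture, or non-AAA death.
  undetected <- function(t0) {
    d_at_t0 <- nat$d0 * exp(nat$growth * t0)
    t_cross <- if (d_at_t0 >= cfg$detection_threshold) t0
               else if (nat$growth > 0) log(cfg$detection_threshold / nat$d0) / nat$growth
               else Inf
    e <- next_incid()
    t_detect <- if (cfg$incidental_hazard > 0 && is.finite(t_cross)) {
      max(t_cross, t0) + e / cfg$incidental_hazard
    } else Inf
    if (t_rup < t_detect && t_rup < t_end) { rupture(t_rup); return(invisible()) }
    if (t_detect >= t_end) return(invisible())
    d_det <- nat$d0 * exp(nat$growth * t_detect)
    if (d_det >= cfg$referral_threshold) {
      add(t_detect, "incidental_detection", 0)
      referral(t_detect, programme = FALSE)
    } else if (d_det >= cfg$detection_threshold) {
      surveillance(t_detect, programme = FALSE)
    } else {
      undetected(t_detect)                # shrank below threshold; try again
    }
  }

  if (screen_detected) {
    d0 <- nat$d0
    if (d0 >= cfg$referral_threshold) {
      referral(0, programme = TRUE)
    } else {
      surveillance(0, programme = TRUE)
    }
  } else {
    undetected(0)
  }

  if (death$cause == "aaa") counts[["aaa_deaths"]] <- counts[["aaa_deaths"]] + 1L
  add(death$time, if (death$cause == "aaa") "aaa_death" else "non_aaa_death", 0)

  keep <- ev_t <= death$time + 1e-12
  ord <- order(ev_t[keep], method = "radix")
  events <- data.frame(time = ev_t[keep][ord], event = ev_e[keep][ord],
                       cost = ev_c[keep][ord])
  list(cost = sum(events$cost * discount_factor(events$time, cfg$discount_rate)),
       qalys = qaly_fn(death$time),
       death_time = death$time, death_cause = death$cause,
       events = events, counts = counts)
}

# --- paired simulation -----------------------------------------------------

#' Simulate one invited/uninvited pair
#'
#' Runs both arms for a single individual.  The invited arm receives an
#' invitation letter at time 0 (with a reinvitation where drawn), attends
#' with the quintile's attendance probability, may need one repeat scan if
#' non-visualised, and is then discharged (diameter < 3.0 cm), enters
#' surveillance (3.0-5.4 cm), or is referred (>= 5.5 cm).  The uninvited
#' arm has identical natural history and can only be detected incidentally.
#' Ruptures lead to emergency repair with configured probability, otherwise
#' immediate AAA death; 30-day operative deaths are AAA deaths.  Costs and
#' QALYs are discounted continuously from entry.
#'
#' @param individual an [make_individual()] object.
#' @param params [load_pathway_params()] output.
#' @param costs [load_cost_schedule()] output.
#' @param hrqol [synth_hrqol_surface()] output.
#' @param config [sim_config()] output.
#' @return an object of class `pair_outcome`: list with elements `invited`
#'   and `uninvited` (each: `cost`, `qalys`, `death_time`, `death_cause`,
#'   `events`, `counts`), plus `inc_cost` and `inc_qaly`.
#' @export
simulate_pair <- function(individual, params, costs, hrqol,
                          config = sim_config()) {
  stopifnot(inherits(individual, "aaa_individual"))
  cfg <- config
  qv <- params$probs[individual$quintile, ]
  q <- as.list(qv)
  t_end <- min(individual$t_death, cfg$age_cap - 65)
  t_rup <- rupture_time_from_exp(individual$d0, individual$growth,
                                 cfg$rupture_alpha, cfg$rupture_beta,
                                 individual$e_rupture, t_end)
  nat <- list(d0 = individual$d0, growth = individual$growth,
              t_end = t_end, t_rup = t_rup, quintile = individual$quintile)
  qaly_fn <- make_qaly_fn(hrqol, individual$quintile, cfg$discount_rate,
                          cfg$age_cap)
  draws <- individual$draws

  uninv <- walk_arm(nat, draws, q, params, costs, cfg, qaly_fn,
                    screen_detected = FALSE)
  uninv$counts <- c(attended = 0L, screen_detected = 0L, uninv$counts)

  # invited arm: letters at t = 0, then either divergence through screen
  # detection or reuse of the uninvited walk plus administrative costs
  letter_events <- data.frame(time = 0, event = "invitation",
                              cost = costs[["invitation"]])
  if (draws$u_reinvite < q$p_reinvite) {
    letter_events <- rbind(letter_events,
                           data.frame(time = 0, event = "reinvitation",
                                      cost = costs[["reinvitation"]]))
  }
  attended <- draws$u_attend < q$p_attend
  scan_events <- NULL
  if (attended) {
    scan_events <- data.frame(time = 0, event = "screening_scan",
                              cost = costs[["screening_scan"]])
    if (draws$u_nonvis < q$p_nonvisualised) {
      scan_events <- rbind(scan_events,
                           data.frame(time = 0, event = "repeat_screening_scan",
                                      cost = costs[["screening_scan"]]))
    }
  }
  detected <- attended && individual$d0 >= cfg$detection_threshold

  if (detected) {
    inv <- walk_arm(nat, draws, q, params, costs, cfg, qaly_fn,
                    screen_detected = TRUE)
  } else {
    inv <- uninv[c("cost", "qalys", "death_time", "death_cause", "events")]
    inv$counts <- uninv$counts[setdiff(names(uninv$counts),
                                       c("attended", "screen_detected"))]
  }
  extra <- rbind(letter_events, scan_events)
  inv$cost <- inv$cost + sum(extra$cost)   # all at t = 0, discount factor 1
  inv$events <- rbind(extra, inv$events)
  inv$events <- inv$events[order(inv$events$time, method = "radix"), ]
  rownames(inv$events) <- NULL
  inv$counts <- c(attended = as.integer(attended),
                  screen_detected = as.integer(detected), inv$counts)

  structure(
    list(invited = inv, uninvited = uninv,
         inc_cost = inv$cost - uninv$cost,
         inc_qaly = inv$qalys - uninv$qalys),
    class = "pair_outcome"
  )
}

# Vectorised cumulative rupture hazard to t_end, with a cheap upper bound to
# avoid the exponential-integral where rupture is impossible.
cumhaz_at_end <- function(d0, g, t_end, alpha, beta) {
  n <- length(d0)
  if (!is.finite(alpha) && alpha < 0) return(rep(0, n))
  d_end <- d0 * exp(pmax(g, 0) * t_end)
  bound <- exp(alpha + beta * d_end) * t_end     # hazard nondecreasing in d
  H <- numeric(n)
  idx <- which(bound > 1e-8)
  for (i in idx) {
    H[i] <- rupture_cumhaz(d0[i], g[i], alpha, beta, t_end[i])
  }
  H
}

#' Run a screened cohort for one quintile
#'
#' Simulates `n` paired lifetimes for one IMD quintile and aggregates
#' incremental costs and QALYs (invited minus uninvited) with Monte-Carlo
#' standard errors, plus pathway event counts per arm.  Fully reproducible
#' given `seed`.  Pairs whose natural history can never involve an AAA
#' (diameter never reaches 3.0 cm, no rupture) are resolved in closed form;
#' the event walk runs for the rest.
#'
#' @param quintile `"Q1"`..`"Q5"`.
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @param params,costs,hrqol,config as for [simulate_pair()].
#' @param diameters a [synth_diameter_model()].
#' @param mortality a [non_aaa_mortality()] table.
#' @return an object of class `quintile_aggregate`: list with `quintile`,
#'   `n`, `seed`, `mean_inc_cost`, `se_inc_cost`, `mean_inc_qaly`,
#'   `se_inc_qaly`, per-arm means, and a `counts` data frame.
#' @export
run_cohort <- function(quintile, n, seed, params, costs, hrqol, diameters,
                       mortality, config = sim_config()) {
  quintile <- match.arg(quintile, QUINTILES)
  if (!is.finite(n) || n < 1) stop_validation("cohort size n must be >= 1")
  n <- as.integer(n)
  cfg <- config
  qv <- as.list(params$probs[quintile, ])

  set.seed(child_seed(seed, match(quintile, QUINTILES)))
  u_tail <- stats::runif(n)
  u_dval <- stats::runif(n)
  g <- stats::rnorm(n, diameters$growth_mean, diameters$growth_sd)
  u_death <- stats::runif(n)
  e_rup <- stats::rexp(n)
  u_attend <- stats::runif(n)
  u_reinvite <- stats::runif(n)
  u_nonvis <- stats::runif(n)
  ind_seed <- sample.int(2147483646L, n, replace = TRUE)

  d0 <- diameter_quantile(diameters, quintile, u_tail, u_dval)
  t_death <- sample_death_times(mortality, quintile, u_death,
                                entry_age = 65, age_cap = cfg$age_cap)
  t_end <- pmin(t_death, cfg$age_cap - 65)

  t_cross <- ifelse(d0 >= cfg$detection_threshold, 0,
                    ifelse(g > 0, log(cfg$detection_threshold / d0) / g, Inf))
  H_end <- cumhaz_at_end(d0, g, t_end, cfg$rupture_alpha, cfg$rupture_beta)
  ruptures_possible <- H_end >= e_rup
  aaa_possible <- (t_cross < t_end) | ruptures_possible

  qaly_fn <- make_qaly_fn(hrqol, quintile, cfg$discount_rate, cfg$age_cap)

  attended <- u_attend < qv$p_attend
  reinvited <- u_reinvite < qv$p_reinvite
  nonvis <- u_nonvis < qv$p_nonvisualised
  letters_cost <- costs[["invitation"]] + reinvited * costs[["reinvitation"]]
  scan_cost <- attended * costs[["screening_scan"]] * (1 + nonvis)

  inc_cost <- letters_cost + scan_cost     # overwritten for AAA-involved pairs
  inc_qaly <- numeric(n)
  qaly_uninv <- qaly_fn(t_end)
  cost_uninv <- numeric(n)
  count_names <- c("attended", "screen_detected", "surveilled", "referred",
                   "elective_repairs", "emergency_repairs", "ruptures",
                   "aaa_deaths")
  counts_inv <- stats::setNames(numeric(8), count_names)
  counts_uninv <- stats::setNames(numeric(8), count_names)
  counts_inv[["attended"]] <- sum(attended)

  for (i in which(aaa_possible)) {
    t_rup_i <- if (ruptures_possible[i]) {
      rupture_time_from_exp(d0[i], g[i], cfg$rupture_alpha, cfg$rupture_beta,
                            e_rup[i], t_end[i])
    } else Inf
    nat <- list(d0 = d0[i], growth = g[i], t_end = t_end[i],
                t_rup = t_rup_i, quintile = quintile)
    draws <- individual_draws(ind_seed[i])
    draws$u_attend <- u_attend[i]
    draws$u_reinvite <- u_reinvite[i]
    draws$u_nonvis <- u_nonvis[i]

    uninv <- walk_arm(nat, draws, qv, params, costs, cfg, qaly_fn,
                      screen_detected = FALSE)
    qaly_uninv[i] <- uninv$qalys
    cost_uninv[i] <- uninv$cost
    counts_uninv[names(uninv$counts)] <- counts_uninv[names(uninv$counts)] +
      uninv$counts

    if (attended[i] && d0[i] >= cfg$detection_threshold) {
      counts_inv[["screen_detected"]] <- counts_inv[["screen_detected"]] + 1
      inv <- walk_arm(nat, draws, qv, params, costs, cfg, qaly_fn,
                      screen_detected = TRUE)
      inc_cost[i] <- letters_cost[i] + scan_cost[i] + inv$cost - uninv$cost
      inc_qaly[i] <- inv$qalys - uninv$qalys
      counts_inv[names(inv$counts)] <- counts_inv[names(inv$counts)] +
        inv$counts
    } else {
      counts_inv[names(uninv$counts)] <- counts_inv[names(uninv$counts)] +
        uninv$counts
    }
  }

  counts <- data.frame(arm = c("invited", "uninvited"),
                       rbind(counts_inv, counts_uninv), row.names = NULL)

  structure(
    list(quintile = quintile, n = n, seed = seed,
         mean_inc_cost = mean(inc_cost),
         se_inc_cost = stats::sd(inc_cost) / sqrt(n),
         mean_inc_qaly = mean(inc_qaly),
         se_inc_qaly = stats::sd(inc_qaly) / sqrt(n),
         mean_cost_uninvited = mean(cost_uninv),
         mean_qaly_uninvited = mean(qaly_uninv),
         se_qaly_uninvited = stats::sd(qaly_uninv) / sqrt(n),
         counts = counts),
    class = "quintile_aggregate"
  )
}

#' @export
print.quintile_aggregate <- function(x, ...) {
  cat(sprintf("Cohort %s (n = %d, seed = %s)\n", x$quintile, x$n,
              format(x$seed)))
  cat(sprintf("  incremental cost: GBP %.2f (MC se %.3f)\n",
              x$mean_inc_cost, x$se_inc_cost))
  cat(sprintf("  incremental QALYs: %.6f (MC se %.6f)\n",
              x$mean_inc_qaly, x$se_inc_qaly))
  print(x$counts)
  invisible(x)
}
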