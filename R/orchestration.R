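# End-to-end orchestration: fixtures -> life table -> simulation -> DCEA,
# with delimited-text outputs and a reproducibility manifest.

#' Load a per-quintile aggregate table
#'
#' Reads a delimited table of per-quintile incremental results (columns
#' `quintile`, `total_cost`, `total_qalys`, and optionally `hoc`,
#' `inc_cost_per_person`, `inc_qaly_per_person`, `eligible_share`),
#' enabling a table-only DCEA without simulation.  The bundled default,
#' `published_aggregates_file()`, carries the reference results of the
#' English AAA screening programme evaluation by deprivation quintile.
#'
#' @param path CSV path; defaults to the bundled reference table.
#' @return data frame with one row per quintile Q1..Q5.
#' @export
load_quintile_aggregates <- function(path = published_aggregates_file()) {
  if (!file.exists(path)) stop_load("aggregate table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("quintile", "total_cost", "total_qalys")
  if (!all(need %in% names(tab))) {
    stop_load("aggregate table needs columns: ", paste(need, collapse = ", "))
  }
  if (!identical(sort(tab$quintile), sort(QUINTILES))) {
    stop_load("aggregate table must have exactly one row per quintile Q1..Q5")
  }
  tab[match(QUINTILES, tab$quintile), ]
}

#' @rdname load_quintile_aggregates
#' @export
published_aggregates_file <- function() {
  system.file("extdata", "published_aggregates.csv", package = "aaadcea",
              mustWork = TRUE)
}

#' Staircase-of-inequality report
#'
#' Summarises per-quintile need/uptake/delivery indicators of the screening
#' pathway (reinvitation, attendance, non-visualisation, surveillance
#' dropout, waits to consultation and surgery), flagging the best and worst
#' quintile on each row.  Higher attendance is better; for every other
#' indicator lower is better.  Rows with identical values across quintiles
#' raise no flags.
#'
#' @param params a [load_pathway_params()] object.
#' @return data frame with columns `item`, `Q1`..`Q5`, `best`, `worst`.
#' @export
staircase_report <- function(params) {
  stopifnot(inherits(params, "pathway_params"))
  items <- c(PATHWAY_PROB_ITEMS, PATHWAY_WAIT_ITEMS)
  higher_better <- items == "p_attend"
  rows <- lapply(seq_along(items), function(i) {
    v <- params$probs[[items[i]]]
    if (length(unique(v)) == 1L) {
      best <- worst <- NA_character_
    } else if (higher_better[i]) {
      best <- QUINTILES[which.max(v)]; worst <- QUINTILES[which.min(v)]
    } else {
      best <- QUINTILES[which.min(v)]; worst <- QUINTILES[which.max(v)]
    }
    data.frame(item = items[i], t(stats::setNames(v, QUINTILES)),
               best = best, worst = worst)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Flatten a dcea_result into a one-row-per-quintile table plus totals row.
dcea_result_table <- function(res) {
  data.frame(
    quintile = c(QUINTILES, "Total"),
    total_cost = c(res$inputs$total_cost, sum(res$inputs$total_cost)),
    total_qalys = c(res$inputs$total_qaly, res$total_qalys),
    hoc = c(res$hoc_per_quintile, res$hoc_total),
    net_health_impact = c(res$population_net, res$net_population_health),
    qale_with = c(res$h1, NA),
    qale_without = c(res$h0, NA)
  )
}

#' Run the full analysis
#'
#' Ties the pipeline together: load pathway and cost tables, build the
#' population profile, generate the synthetic diameter, HRQoL and mortality
#' fixtures, derive the non-AAA life table, simulate all five quintile
#' cohorts, and run the DCEA for the base case plus the equal-opportunity-
#' cost and leveling-up scenarios.  Writes delimited results tables and a
#' run manifest (seed, config hash, file provenance) to `output_dir`.
#'
#' @param config a named list or path to a YAML file.  Recognised keys
#'   (all optional): `seed`, `n_per_quintile`, `k`, `epsilon`,
#'   `pathway_params`, `costs` (paths), `scenario`
#'   (`"all"`, `"base"`, `"equal_hoc"`, `"leveling_up"`, or
#'   `"table_only"`), `aggregates` (path, used by `table_only`), `sim`
#'   (sub-list of [sim_config()] overrides), `profile` (sub-list of
#'   [population_profile()] overrides), `diameter` (sub-list of
#'   [synth_diameter_model()] overrides), `mortality_gradient`
#'   (length-5 rate multipliers), `output_dir`.
#' @param output_dir where outputs are written (default
#'   `config$output_dir`, else a temporary directory).
#' @return invisibly, a list with the aggregates, DCEA results, staircase
#'   table, and the manifest.
#' @export
run_full_analysis <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  n_per_quintile <- config$n_per_quintile %||% 50000L
  k <- config$k %||% 13000
  epsilon <- config$epsilon %||% 3.5
  scenario <- config$scenario %||% "all"
  output_dir <- output_dir %||% config$output_dir %||%
    file.path(tempdir(), "aaadcea-run")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  params_path <- config$pathway_params %||% pathway_params_file()
  costs_path <- config$costs %||% cost_schedule_file()
  for (p in c(params_path, costs_path)) {
    if (!file.exists(p)) stop_load("input path does not exist: ", p)
  }
  params <- load_pathway_params(params_path)
  costs <- load_cost_schedule(costs_path)
  profile <- do.call(population_profile, config$profile %||% list())
  staircase <- staircase_report(params)

  results <- list()
  aggregates <- NULL

  if (scenario == "table_only") {
    agg_path <- config$aggregates %||% published_aggregates_file()
    tab <- load_quintile_aggregates(agg_path)
    inputs <- dcea_inputs(profile, total_cost = tab$total_cost,
                          total_qaly = tab$total_qalys,
                          k = k, epsilon = epsilon,
                          hoc_i = if ("hoc" %in% names(tab)) tab$hoc else NULL)
    results$base <- dcea(inputs)
    results$equal_hoc <- run_scenario(inputs, "equal_hoc")
  } else {
    sim_cfg <- do.call(sim_config, config$sim %||% list())
    diameters <- do.call(synth_diameter_model,
                         c(config$diameter %||% list(),
                           list(seed = child_seed(seed, 1000L))))
    hrqol <- synth_hrqol_surface(age_cap = sim_cfg$age_cap)
    mort_inputs <- synth_mortality_inputs(ages = 65:(sim_cfg$age_cap - 1))
    mortality <- non_aaa_mortality(mort_inputs, sex = "male")
    gradient <- config$mortality_gradient %||% c(1.30, 1.15, 1.00, 0.88, 0.78)
    mortality <- apply_rate_gradient(mortality, gradient)

    message("simulating ", n_per_quintile, " pairs per quintile (seed ",
            seed, ")")
    aggregates <- lapply(QUINTILES, function(q) {
      run_cohort(q, n_per_quintile, seed, params, costs, hrqol, diameters,
                 mortality, sim_cfg)
    })
    names(aggregates) <- QUINTILES
    inputs <- dcea_inputs(
      profile,
      inc_cost = vapply(aggregates, `[[`, numeric(1), "mean_inc_cost"),
      inc_qaly = vapply(aggregates, `[[`, numeric(1), "mean_inc_qaly"),
      k = k, epsilon = epsilon
    )
    if (scenario %in% c("all", "base")) results$base <- dcea(inputs)
    if (scenario %in% c("all", "equal_hoc")) {
      results$equal_hoc <- run_scenario(inputs, "equal_hoc")
    }
    if (scenario %in% c("all", "leveling_up")) {
      bundle <- list(params = params, costs = costs, hrqol = hrqol,
                     diameters = diameters, mortality = mortality,
                     n = n_per_quintile, seed = child_seed(seed, 2000L),
                     config = sim_cfg)
      results$leveling_up <- run_scenario(inputs, "leveling_up", bundle)
    }
    message("uncalibrated synthetic defaults in force: rupture hazard, ",
            "incidental detection, turn-down, reintervention")
  }

  # --- write outputs -------------------------------------------------------
  wr <- function(df, name) {
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  }
  wr(staircase, "staircase.csv")
  if (!is.null(aggregates)) {
    agg_tab <- do.call(rbind, lapply(aggregates, function(a) {
      data.frame(quintile = a$quintile, n = a$n,
                 mean_inc_cost = a$mean_inc_cost, se_inc_cost = a$se_inc_cost,
                 mean_inc_qaly = a$mean_inc_qaly, se_inc_qaly = a$se_inc_qaly)
    }))
    wr(agg_tab, "aggregates.csv")
  }
  ede_curves <- NULL
  equity <- NULL
  for (nm in names(results)) {
    res <- results[[nm]]
    wr(dcea_result_table(res), paste0("dcea_", nm, ".csv"))
    cv <- res$threshold$curve
    cv$scenario <- nm
    ede_curves <- rbind(ede_curves, cv)
    equity <- rbind(equity,
                    data.frame(scenario = nm,
                               inequality_value = res$inequality_value,
                               net_population_health = res$net_population_health))
  }
  if (!is.null(ede_curves)) wr(ede_curves, "ede_curves.csv")
  if (!is.null(equity)) wr(equity, "equity_plane.csv")

  cfg_file <- file.path(output_dir, "config_resolved.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aaadcea")),
    seed = seed,
    n_per_quintile = n_per_quintile,
    scenario = scenario,
    k = k, epsilon = epsilon,
    rho_k = as.list(if (!is.null(results$equal_hoc) && scenario == "equal_hoc")
      results$equal_hoc$inputs$profile$rho_k else profile$rho_k),
    config_hash = unname(tools::md5sum(cfg_file)),
    inputs = list(pathway_params = params_path, costs = costs_path)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(aggregates = aggregates, results = results,
                 staircase = staircase, manifest = manifest,
                 output_dir = output_dir))
}
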