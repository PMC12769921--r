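# Unit costs of the screening programme and AAA repair, GBP 2020/2021.

COST_ITEMS <- c(
  "invitation", "reinvitation", "screening_scan", "surveillance_scan",
  "surveillance_scan_turndown", "consultation",
  "elective_evar", "elective_open", "emergency_evar", "emergency_open",
  "reintervention_elective_evar", "reintervention_elective_open",
  "reintervention_emergency_evar", "reintervention_emergency_open",
  "surveillance_post_evar", "surveillance_post_open"
)

#' Load the cost schedule
#'
#' Reads the 16-item unit-cost table (GBP, 2020/2021 prices): invitation and
#' reinvitation letters, screening and surveillance scans (including the
#' post-turn-down tariff), consultation for elective surgery, the four repair
#' procedures (elective/emergency x EVAR/open), reintervention after each,
#' and post-repair surveillance.  The bundled default is `cost_schedule_file()`.
#'
#' @param path path to a CSV file with columns `item` and `cost`.
#' @return an object of class `cost_schedule`: a named numeric vector over
#'   the 16 items.
#' @export
load_cost_schedule <- function(path = cost_schedule_file()) {
  if (!file.exists(path)) stop_load("cost schedule file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "cost") %in% names(tab))) {
    stop_load("cost schedule needs 'item' and 'cost' columns")
  }
  missing_items <- setdiff(COST_ITEMS, tab$item)
  if (length(missing_items)) {
    stop_load("cost schedule missing item(s): ",
              paste(missing_items, collapse = ", "))
  }
  costs <- stats::setNames(tab$cost, tab$item)[COST_ITEMS]
  if (any(!is.finite(costs))) {
    stop_load("non-numeric cost for item '", COST_ITEMS[!is.finite(costs)][1], "'")
  }
  if (any(costs < 0)) {
    stop_validation("negative cost for item '", COST_ITEMS[costs < 0][1], "'")
  }
  structure(costs, class = "cost_schedule")
}

#' @rdname load_cost_schedule
#' @export
cost_schedule_file <- function() {
  system.file("extdata", "costs.csv", package = "aaadcea", mustWork = TRUE)
}

#' Write a cost schedule back to delimited text
#'
#' @param costs a `cost_schedule` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_schedule <- function(costs, path) {
  stopifnot(inherits(costs, "cost_schedule"))
  utils::write.csv(data.frame(item = names(costs), cost = as.numeric(costs)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat("Cost schedule (GBP 2020/2021)\n")
  print(data.frame(item = names(x), cost = sprintf("%.2f", as.numeric(x)),
                   row.names = NULL))
  invisible(x)
}
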