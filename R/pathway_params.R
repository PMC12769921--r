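# Screening pathway parameters: per-quintile access/uptake probabilities,
# waiting times, and the logistic models governing repair type and 30-day
# operative mortality.

PATHWAY_PROB_ITEMS <- c("p_reinvite", "p_attend", "p_nonvisualised", "p_dropout")
PATHWAY_WAIT_ITEMS <- c("wait_consult", "wait_surgery")
PATHWAY_LOGIT_ITEMS <- c(
  "elective_open_intercept", "elective_open_age", "elective_open_aorta",
  "emergency_open_intercept", "emergency_open_age",
  "mort_elective_evar_intercept", "mort_elective_evar_age", "mort_elective_evar_aorta",
  "mort_elective_open_intercept", "mort_elective_open_age", "mort_elective_open_aorta",
  "mort_emergency_evar_intercept", "mort_emergency_evar_age",
  "mort_emergency_open_intercept", "mort_emergency_open_age"
)
PATHWAY_ITEMS <- c(PATHWAY_PROB_ITEMS, PATHWAY_WAIT_ITEMS, PATHWAY_LOGIT_ITEMS)

#' Load per-quintile screening pathway parameters
#'
#' Reads the delimited parameter table (one row per item, one column per IMD
#' quintile `Q1`..`Q5`, optional `best_case` column naming the quintile whose
#' value represents best-case access or delivery).  The bundled default,
#' `pathway_params_file()`, transcribes the published screening, attendance,
#' surveillance, and treatment parameters: reinvitation, attendance,
#' non-visualisation and surveillance-dropout probabilities; mean waits to
#' consultation and elective surgery (years); and logistic-regression
#' coefficients (log-odds scale) for elective/emergency open-vs-EVAR repair
#' choice and for 30-day operative mortality by repair type and setting.
#'
#' Aorta size enters the logistic models in millimetres: with printed
#' coefficients of order 0.01-0.03 per unit, a centimetre scale would make
#' the aorta term negligible against the intercepts.
#'
#' @param path path to a CSV file; defaults to the bundled table.
#' @return an object of class `pathway_params`: a list with
#'   \describe{
#'     \item{probs}{5-row data frame (`Q1`..`Q5`) of the four pathway
#'       probabilities and the two waits.}
#'     \item{logit_elective_open, logit_emergency_open}{5 x k coefficient
#'       matrices (intercept, age, and, for elective, aorta size in mm).}
#'     \item{mortality_logits}{named list of shared coefficient vectors for
#'       the four 30-day operative mortality models.}
#'     \item{best_case}{named character vector, item -> quintile flagged as
#'       best case (`NA` where no flag).}
#'   }
#' @export
load_pathway_params <- function(path = pathway_params_file()) {
  if (!file.exists(path)) stop_load("pathway parameter file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"item" %in% names(tab)) stop_load("pathway table lacks an 'item' column")
  missing_q <- setdiff(QUINTILES, names(tab))
  if (length(missing_q)) {
    stop_load("pathway table lacks quintile column(s): ",
              paste(missing_q, collapse = ", "))
  }
  missing_items <- setdiff(PATHWAY_ITEMS, tab$item)
  if (length(missing_items)) {
    stop_load("pathway table missing item(s): ",
              paste(missing_items, collapse = ", "))
  }
  for (q in QUINTILES) {
    bad <- !is.finite(tab[[q]])
    if (any(bad)) {
      stop_load("pathway table cell is not numeric: item '",
                tab$item[bad][1], "', quintile ", q)
    }
  }

  rownames(tab) <- tab$item
  val <- function(item) unlist(tab[item, QUINTILES], use.names = FALSE)

  probs <- data.frame(row.names = QUINTILES)
  for (item in PATHWAY_PROB_ITEMS) {
    v <- val(item)
    check_probability(v, item)
    probs[[item]] <- v
  }
  for (item in PATHWAY_WAIT_ITEMS) {
    v <- val(item)
    check_nonnegative(v, item)
    probs[[item]] <- v
  }

  coef_matrix <- function(stub, terms) {
    m <- sapply(terms, function(term) val(paste0(stub, "_", term)))
    rownames(m) <- QUINTILES
    m
  }
  logit_elective_open <- coef_matrix("elective_open", c("intercept", "age", "aorta"))
  logit_emergency_open <- coef_matrix("emergency_open", c("intercept", "age"))

  shared <- function(stub, terms) {
    v <- vapply(terms, function(term) {
      row <- val(paste0(stub, "_", term))
      if (length(unique(row)) != 1L) {
        stop_load("coefficient '", stub, "_", term,
                  "' is shared across quintiles but differs in the file")
      }
      row[1]
    }, numeric(1))
    stats::setNames(v, terms)
  }
  mortality_logits <- list(
    elective_evar  = shared("mort_elective_evar", c("intercept", "age", "aorta")),
    elective_open  = shared("mort_elective_open", c("intercept", "age", "aorta")),
    emergency_evar = shared("mort_emergency_evar", c("intercept", "age")),
    emergency_open = shared("mort_emergency_open", c("intercept", "age"))
  )

  best_raw <- if ("best_case" %in% names(tab)) tab$best_case else rep("", nrow(tab))
  best_raw[is.na(best_raw)] <- ""
  best_case <- stats::setNames(ifelse(best_raw == "", NA_character_, best_raw), tab$item)
  bad_flag <- !is.na(best_case) & !(best_case %in% QUINTILES)
  if (any(bad_flag)) {
    stop_load("best_case flag must name a quintile Q1..Q5; item '",
              names(best_case)[bad_flag][1], "' has '", best_case[bad_flag][1], "'")
  }
  best_case <- best_case[PATHWAY_ITEMS]

  structure(
    list(probs = probs,
         logit_elective_open = logit_elective_open,
         logit_emergency_open = logit_emergency_open,
         mortality_logits = mortality_logits,
         best_case = best_case),
    class = "pathway_params"
  )
}

#' @rdname load_pathway_params
#' @export
pathway_params_file <- function() {
  system.file("extdata", "pathway_params.csv", package = "aaadcea", mustWork = TRUE)
}

#' Write pathway parameters back to delimited text
#'
#' Inverse of [load_pathway_params()]; a written table reloads
#' value-identically.
#'
#' @param params a `pathway_params` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pathway_params <- function(params, path) {
  stopifnot(inherits(params, "pathway_params"))
  rows <- lapply(PATHWAY_ITEMS, function(item) {
    v <- pathway_item_values(params, item)
    data.frame(item = item, t(stats::setNames(v, QUINTILES)),
               best_case = ifelse(is.na(params$best_case[[item]]), "",
                                  params$best_case[[item]]))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-quintile value vector for any table item (shared logits recycled).
pathway_item_values <- function(params, item) {
  if (item %in% c(PATHWAY_PROB_ITEMS, PATHWAY_WAIT_ITEMS)) {
    return(params$probs[[item]])
  }
  if (grepl("^elective_open_", item)) {
    term <- sub("^elective_open_", "", item)
    return(params$logit_elective_open[, term])
  }
  if (grepl("^emergency_open_", item)) {
    term <- sub("^emergency_open_", "", item)
    return(params$logit_emergency_open[, term])
  }
  stub <- sub("_(intercept|age|aorta)$", "", sub("^mort_", "", item))
  term <- sub("^.*_(intercept|age|aorta)$", "\\1", item)
  rep(params$mortality_logits[[stub]][[term]], 5)
}

#' Leveling-up parameter assembly
#'
#' Builds the counterfactual parameter set in which every quintile receives
#' the best-case value of each access/uptake/delivery parameter, i.e. each
#' best-case-flagged row has its flagged quintile's value copied to all
#' quintiles.  Unflagged rows (including reinvitation and the shared
#' operative-mortality models) are left quintile-specific, as are
#' eligibility and costs.
#'
#' @param params a `pathway_params` object.
#' @return a `pathway_params` object with best-case values propagated.
#' @export
leveling_up_params <- function(params) {
  stopifnot(inherits(params, "pathway_params"))
  out <- params
  for (item in names(params$best_case)) {
    q <- params$best_case[[item]]
    if (is.na(q)) next
    qi <- match(q, QUINTILES)
    if (item %in% c(PATHWAY_PROB_ITEMS, PATHWAY_WAIT_ITEMS)) {
      out$probs[[item]] <- rep(params$probs[[item]][qi], 5)
    } else if (grepl("^elective_open_", item)) {
      term <- sub("^elective_open_", "", item)
      out$logit_elective_open[, term] <- params$logit_elective_open[qi, term]
    } else if (grepl("^emergency_open_", item)) {
      term <- sub("^emergency_open_", "", item)
      out$logit_emergency_open[, term] <- params$logit_emergency_open[qi, term]
    }
  }
  out
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("Screening pathway parameters (per IMD quintile)\n")
  print(round(x$probs, 4))
  flagged <- x$best_case[!is.na(x$best_case)]
  if (length(flagged)) {
    cat("best-case flags:",
        paste(names(flagged), flagged, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
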