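# Repair type choice and 30-day operative mortality, from the published
# logistic models (log-odds with age and, where fitted, aorta size in mm).

#' Repair choice and 30-day operative mortality
#'
#' Chooses open repair versus EVAR from the quintile-specific logistic model
#' for the given setting, then draws 30-day operative death from the
#' (quintile-shared) mortality model for that setting and repair type.  Age
#' is in years; aorta size in millimetres, the unit the coefficient
#' magnitudes imply.
#'
#' The printed emergency 30-day mortality models imply low absolute
#' mortality at typical ages (e.g. about 1.6% for emergency EVAR at 75);
#' they are implemented exactly as printed — see the methods vignette.
#'
#' @param quintile `"Q1"`..`"Q5"`.
#' @param setting `"elective"` or `"emergency"`.
#' @param age age at repair in years.
#' @param aorta aortic diameter at repair in millimetres (used by the
#'   elective choice model and both elective mortality models).
#' @param params a [load_pathway_params()] object.
#' @param u optional named uniforms `c(choice=, death=)` for deterministic
#'   paired draws; drawn from the RNG stream if missing.
#' @return list with `type` (`"open"` or `"evar"`), `died` (logical 30-day
#'   operative death), `p_open`, `p_death`.
#' @export
repair_choice_and_mortality <- function(quintile, setting, age, aorta, params,
                                        u = NULL) {
  quintile <- match.arg(quintile, QUINTILES)
  if (!setting %in% c("elective", "emergency")) {
    stop_validation("unknown setting '", setting, "' (elective or emergency)")
  }
  u <- u %||% c(choice = stats::runif(1), death = stats::runif(1))

  if (setting == "elective") {
    cf <- params$logit_elective_open[quintile, ]
    logit_open <- cf[["intercept"]] + cf[["age"]] * age + cf[["aorta"]] * aorta
  } else {
    cf <- params$logit_emergency_open[quintile, ]
    logit_open <- cf[["intercept"]] + cf[["age"]] * age
  }
  p_open <- expit(logit_open)
  type <- if (u[["choice"]] < p_open) "open" else "evar"

  mk <- paste(setting, type, sep = "_")
  mcf <- params$mortality_logits[[mk]]
  logit_death <- mcf[["intercept"]] + mcf[["age"]] * age
  if ("aorta" %in% names(mcf)) logit_death <- logit_death + mcf[["aorta"]] * aorta
  p_death <- expit(logit_death)

  list(type = type, died = u[["death"]] < p_death,
       p_open = p_open, p_death = p_death)
}
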