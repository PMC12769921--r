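# Synthetic baseline aortic diameter model.  The registry distributions of
# aortic size at 65 are not redistributable, so baseline diameters are drawn
# from a two-component mixture: a lognormal "body" of non-aneurysmal aortas
# truncated below 3.0 cm, plus a shifted-lognormal aneurysm tail above
# 3.0 cm whose weight (the AAA prevalence) rises with deprivation.

#' Synthetic baseline aortic diameter model
#'
#' Builds the per-quintile mixture model for aortic diameter at age 65 and
#' the between-individual distribution of annual exponential growth rates.
#' The deprivation gradient is parameterised by the Q5 (least deprived)
#' prevalence of diameter >= 3.0 cm and the Q1:Q5 prevalence ratio; the
#' default ratio 2.0 reflects AAA being about twice as common in the most
#' deprived areas as in the least deprived.  Intermediate quintiles are
#' interpolated log-linearly.
#'
#' Growth-rate and mixture shape defaults are uncalibrated synthetic
#' choices (the source registries' distributions are unpublished) and are
#' documented in the methods vignette.
#'
#' @param prevalence_q5 P(baseline diameter >= 3.0 cm) in Q5; default 0.011.
#' @param ratio_q1_q5 Q1:Q5 prevalence ratio; must be >= 1. Default 2.0.
#' @param body_meanlog,body_sdlog lognormal parameters of the non-aneurysmal
#'   component (cm scale; default median 2.0 cm).
#' @param tail_meanlog,tail_sdlog lognormal parameters of the aneurysm
#'   excess over 3.0 cm (default median about 3.6 cm overall).
#' @param growth_mean,growth_sd population mean and between-individual SD of
#'   the annual exponential diameter growth rate (per year).
#' @param seed integer seed stored with the model; [sample_baseline_diameters()]
#'   uses it for reproducible draws.
#' @return an object of class `diameter_model`.
#' @export
synth_diameter_model <- function(prevalence_q5 = 0.011,
                                 ratio_q1_q5 = 2.0,
                                 body_meanlog = log(2.0),
                                 body_sdlog = 0.10,
                                 tail_meanlog = log(0.6),
                                 tail_sdlog = 0.6,
                                 growth_mean = 0.010,
                                 growth_sd = 0.008,
                                 seed = 1L) {
  if (!is.finite(ratio_q1_q5) || ratio_q1_q5 < 1) {
    stop_validation("ratio_q1_q5 must be >= 1; got ", ratio_q1_q5)
  }
  if (!is.finite(prevalence_q5) || prevalence_q5 < 0 || prevalence_q5 >= 1) {
    stop_validation("prevalence_q5 must lie in [0, 1); got ", prevalence_q5)
  }
  check_nonnegative(c(body_sdlog, tail_sdlog, growth_sd), "scale parameters")
  if (body_sdlog <= 0 || tail_sdlog <= 0) {
    stop_validation("distribution scales must be positive")
  }

  prevalence <- if (prevalence_q5 == 0) {
    rep(0, 5)
  } else {
    # log-linear interpolation from Q1 = ratio * Q5 down to Q5
    exp(seq(log(prevalence_q5 * ratio_q1_q5), log(prevalence_q5), length.out = 5))
  }
  if (any(prevalence >= 1)) {
    stop_validation("implied quintile prevalence reaches 1; lower prevalence_q5 or ratio")
  }

  structure(
    list(prevalence = stats::setNames(prevalence, QUINTILES),
         body_meanlog = body_meanlog, body_sdlog = body_sdlog,
         tail_meanlog = tail_meanlog, tail_sdlog = tail_sdlog,
         growth_mean = growth_mean, growth_sd = growth_sd,
         threshold = 3.0, seed = as.integer(seed)),
    class = "diameter_model"
  )
}

# Deterministic inverse-CDF draw from the mixture given two uniforms, so the
# same uniforms always map to the same diameter (common-random-number
# friendly).  u_tail selects the component, u_val the value within it.
diameter_quantile <- function(model, quintile, u_tail, u_val) {
  p <- model$prevalence[[quintile]]
  is_tail <- u_tail < p
  # body truncated strictly below the 3.0 cm threshold
  p_below <- stats::plnorm(model$threshold, model$body_meanlog, model$body_sdlog)
  body <- stats::qlnorm(u_val * p_below, model$body_meanlog, model$body_sdlog)
  tail_d <- model$threshold +
    stats::qlnorm(u_val, model$tail_meanlog, model$tail_sdlog)
  ifelse(is_tail, tail_d, pmin(body, model$threshold - 1e-9))
}

#' Sample baseline diameters and growth rates
#'
#' Draws `n` baseline aortic diameters (cm) for one quintile from a
#' [synth_diameter_model()], reproducibly from the model's stored seed.
#' `sample_growth_rates()` draws individual annual exponential growth rates
#' from the model's normal between-individual distribution.
#'
#' @param model a `diameter_model`.
#' @param quintile `"Q1"`..`"Q5"`.
#' @param n number of draws.
#' @param seed overrides the model seed if given.
#' @return numeric vector of length `n`.
#' @export
sample_baseline_diameters <- function(model, quintile, n, seed = NULL) {
  stopifnot(inherits(model, "diameter_model"))
  quintile <- match.arg(quintile, QUINTILES)
  seed <- seed %||% child_seed(model$seed, match(quintile, QUINTILES))
  set.seed(seed)
  diameter_quantile(model, quintile, stats::runif(n), stats::runif(n))
}

#' @rdname sample_baseline_diameters
#' @export
sample_growth_rates <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "diameter_model"))
  seed <- seed %||% child_seed(model$seed, 97L)
  set.seed(seed)
  stats::rnorm(n, model$growth_mean, model$growth_sd)
}
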