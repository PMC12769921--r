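# Shared helpers: inverse logit, continuous discounting, validation.

QUINTILES <- paste0("Q", 1:5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse logit
#'
#' @param x log-odds.
#' @return `exp(x) / (1 + exp(x))`, computed stably; `expit(-Inf)` is 0 and
#'   `expit(Inf)` is 1.
#' @export
expit <- function(x) {
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' Continuous discount factor and integral
#'
#' Discounting is continuous at an annual rate `rate` (factor
#' `(1 + rate)^-t`), with `t` measured in years since entry (age 65).
#' `discount_integral(t1, t2)` is the integral of the discount factor over
#' `[t1, t2]`, i.e. the discounted value of one unit accrued continuously
#' over that interval.
#'
#' @param t,t1,t2 times in years since entry.
#' @param rate annual discount rate (default 0.035).
#' @return numeric vector.
#' @export
discount_factor <- function(t, rate = 0.035) {
  (1 + rate)^(-t)
}

#' @rdname discount_factor
#' @export
discount_integral <- function(t1, t2, rate = 0.035) {
  if (rate == 0) return(pmax(t2 - t1, 0))
  lr <- log1p(rate)
  out <- (discount_factor(t1, rate) - discount_factor(t2, rate)) / lr
  pmax(out, 0)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("aaadcea_validation_error", "error")))
}

stop_load <- function(...) {
  stop(errorCondition(paste0(...), class = c("aaadcea_load_error", "error")))
}

check_probability <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_validation(what, " must lie in [0, 1]; got ",
                    paste(signif(x, 6), collapse = ", "))
  }
  invisible(x)
}

check_nonnegative <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_validation(what, " must be nonnegative; got ",
                    paste(signif(x, 6), collapse = ", "))
  }
  invisible(x)
}

# Derive a reproducible child seed from a base seed and a small offset,
# kept within the 32-bit integer range R requires for set.seed().
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}
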