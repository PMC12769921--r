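# AAA natural history: exponential diameter growth and a diameter-driven
# log-linear rupture hazard, the canonical joint growth/rupture formulation
# for AAA microsimulation.

#' Aortic diameter trajectory
#'
#' Exponential growth: log-diameter linear in time with an
#' individual-specific annual rate, `d(t) = d0 * exp(g * t)`.
#'
#' @param individual an object from [make_individual()], or a list with
#'   fields `d0` (baseline diameter, cm) and `growth` (per year).
#' @param t time in years since entry (age 65); `t >= 0`.
#' @return diameter in cm; continuous, equal to `d0` at `t = 0`, and
#'   nondecreasing in `t` whenever `growth >= 0`.
#' @export
diameter_at <- function(individual, t) {
  if (any(t < 0)) stop_validation("t must be nonnegative")
  individual$d0 * exp(individual$growth * t)
}

# Cumulative rupture hazard over [0, T] for d(t) = d0 exp(g t) and hazard
# lambda(t) = exp(alpha + beta d(t)).  Substituting u = beta d0 exp(g t)
# gives H(T) = exp(alpha)/g * [Ei(u(T)) - Ei(u(0))] (exponential integral);
# for g = 0 the hazard is constant.
rupture_cumhaz <- function(d0, g, alpha, beta, T) {
  if (beta == 0 || !is.finite(alpha)) {
    if (!is.finite(alpha) && alpha < 0) return(rep(0, length(T)))
    return(exp(alpha) * T)
  }
  if (abs(g) < 1e-12) {
    return(exp(alpha + beta * d0) * T)
  }
  u0 <- beta * d0
  uT <- u0 * exp(g * T)
  (exp(alpha) / g) * (pracma::expint_Ei(uT) - pracma::expint_Ei(u0))
}

# Invert H(T) = target on [0, t_max]; returns Inf if H(t_max) < target.
rupture_time_from_exp <- function(d0, g, alpha, beta, e_draw, t_max) {
  if (e_draw <= 0) return(0)
  H_max <- rupture_cumhaz(d0, g, alpha, beta, t_max)
  if (!is.finite(H_max) || H_max < e_draw) {
    if (!is.finite(H_max) && H_max > 0) {
      # numerically overflowed cumulative hazard: rupture is certain
    } else {
      return(Inf)
    }
  }
  if (beta == 0 || abs(g) < 1e-12) {
    lam <- exp(alpha + beta * d0)
    if (lam <= 0) return(Inf)
    return(min(e_draw / lam, t_max))
  }
  f <- function(t) rupture_cumhaz(d0, g, alpha, beta, t) - e_draw
  stats::uniroot(f, c(0, t_max), tol = 1e-9)$root
}

#' Sample a rupture time
#'
#' Draws the rupture time from the inhomogeneous hazard
#' `lambda(t) = exp(alpha + beta * d(t))` along the individual's growth
#' trajectory, by inverting the cumulative hazard at a unit-exponential
#' draw.  The hazard describes biology only: it is identical in the invited
#' and uninvited arms (screening changes detection, not rupture risk), and
#' the same exponential draw always yields the same rupture time.
#'
#' @param individual as for [diameter_at()].
#' @param alpha,beta hazard intercept and slope (per cm of diameter).
#'   Defaults `alpha = -17`, `beta = 2.5` give a negligible hazard below
#'   3 cm and roughly 4%/year at 5.5 cm; they are uncalibrated synthetic
#'   defaults.
#' @param e_draw optional unit-exponential draw; if missing one is drawn
#'   from the current RNG stream.
#' @param t_max horizon in years (default 45, i.e. to age 110).
#' @return rupture time in years since entry, possibly `Inf` (no rupture
#'   within the horizon).
#' @export
sample_rupture_time <- function(individual, alpha = -17, beta = 2.5,
                                e_draw = NULL, t_max = 45) {
  e_draw <- e_draw %||% stats::rexp(1)
  rupture_time_from_exp(individual$d0, individual$growth, alpha, beta,
                        e_draw, t_max)
}
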