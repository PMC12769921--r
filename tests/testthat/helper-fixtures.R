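# Shared fixtures and independent oracles, built in code.

default_params <- load_pathway_params()
default_costs <- load_cost_schedule()

# Tiny mortality inputs with hand-controllable numbers: one age-sex stratum
# style toy used by the lifetable tests.
toy_mortality_inputs <- function(all_cause, aaa, pop_by_quintile,
                                 age = 70, sex = "male") {
  deaths <- data.frame(age = age, sex = sex, all_cause = all_cause, aaa = aaa)
  population <- data.frame(age = age, sex = sex,
                           quintile = paste0("Q", seq_along(pop_by_quintile)),
                           population = pop_by_quintile)
  mortality_inputs(deaths, population)
}

# A small but full synthetic mortality table for the simulator.
sim_mortality <- function(gradient = c(1.30, 1.15, 1.00, 0.88, 0.78)) {
  apply_rate_gradient(non_aaa_mortality(synth_mortality_inputs()), gradient)
}

# Independent discounted-QALY oracle: utility piecewise constant over single
# years of age, continuous discounting — computed from exported primitives
# only, not via the simulator's internal accumulator.
oracle_qalys <- function(death_time, quintile, surface, rate = 0.035) {
  vapply(death_time, function(T) {
    if (T <= 0) return(0)
    ks <- seq_len(ceiling(T)) - 1
    sum(utility_at(surface, 65 + ks, quintile) *
          discount_integral(ks, pmin(ks + 1, T), rate))
  }, numeric(1))
}

# Independent Atkinson EDE oracle: direct evaluation of the closed form.
oracle_ede <- function(h, n, eps) {
  w <- n / sum(n)
  if (eps == 1) exp(sum(w * log(h))) else sum(w * h^(1 - eps))^(1 / (1 - eps))
}
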