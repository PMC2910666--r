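# Shared fixtures: the canonical parameter sets used across the suite.

logistic_normal <- function() growth_law(rate = 0.4, capacity = 1e6)
logistic_tumor <- function() growth_law(rate = 0.3, capacity = 1.2e6)
gompertz_lovo <- function(capacity = 1e5)
  growth_law(rate = 0.083, capacity = capacity, shape = 0)

default_ia <- function(...) {
  args <- list(...)
  do.call(interaction_params,
          utils::modifyList(list(beta = 2, k = 1, t_crit = 3e5, rho0 = 1,
                                 rho1 = 1000, k_scale = 1.2e6), args))
}

decoupled_spec <- function(t_end = 100, tumor = logistic_tumor(), ...)
  model_spec(normal = logistic_normal(), tumor = tumor, interaction = NULL,
             N0 = 1, T0 = 1, t_end = t_end, ...)

# Integrate a single growth law numerically with tight tolerances; the
# independent numerical route set against closed_form_population().
integrate_growth_law <- function(law, x0, times) {
  out <- deSolve::ode(y = c(x = x0), times = times,
                      func = function(t, y, p) list(growth_flux(max(y, 0), law)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-8)
  unname(out[, "x"])
}
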