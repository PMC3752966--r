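# shared fixtures: the published ERSPC-Rotterdam quadratic and its
# first-round prevalence
fig_model <- function() erspc_incidence()
fig_prevalence <- 0.04

# independent root oracle: invert cumulative incidence by bisection
root_oracle <- function(f, target, lower = 1e-9, upper = 100) {
  stats::uniroot(function(m) f(m) - target, c(lower, upper),
                 tol = 1e-12)$root
}

# quadrature oracle for weighted sojourn moments, E[g(Y)] under exp(mu)
exp_expect <- function(g, mu, upper = 60 * mu) {
  stats::integrate(function(y) g(y) * dexp(y, 1 / mu), 0, upper,
                   rel.tol = 1e-10, subdivisions = 1000L)$value
}
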