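# Shared fixtures: toy PK parameter sets and regimens built in code.

toy_one_cmt <- function() pk_parameters(cl = 5, v1 = 10)

toy_three_cmt <- function() {
  pk_parameters(cl = 8, v1 = 12, q = c(20, 3), v = c(30, 200))
}

# random but physiological-ish mammillary parameter sets for property tests
random_pk_params <- function(n_compartments = sample(1:3, 1)) {
  k <- n_compartments - 1
  pk_parameters(
    cl = stats::runif(1, 1, 60),
    v1 = stats::runif(1, 5, 50),
    q = if (k > 0) stats::runif(k, 1, 40) else numeric(),
    v = if (k > 0) stats::runif(k, 10, 500) else numeric()
  )
}

# regimen with no modification rules: pure BSA dosing
flat_regimen <- function(dose = 20, duration = 1) {
  regimen("flat", standard_dose = dose, infusion_duration = duration)
}

# numerical ODE oracle for the infusion profile (mg amounts -> ug/L),
# independent of the closed-form eigen solver
ode_profile_oracle <- function(params, dose, tinf, times) {
  K <- doxadapt:::rate_matrix(params)
  rate <- dose / tinf
  deriv <- function(t, y, p) {
    input <- if (t <= tinf) rate else 0
    list(as.vector(K %*% y) + c(input, rep(0, nrow(K) - 1)))
  }
  out <- deSolve::lsoda(y = rep(0, nrow(K)), times = times, func = deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  out[, 2] / params$v1 * 1000
}
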