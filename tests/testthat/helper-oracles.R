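# Shared fixtures and independent oracles.

# final population typical values (school-age OAB model)
final_2cpt_params <- function() {
  structural_params(cl_f = 8.81, v2_f = 162, q_f = 98.1, v3_f = 174,
                    ka = 0.742, alag = 0.834, f_rel = 1)
}

# numeric integration of the absorption + disposition ODE system (oracle
# for the closed-form solutions)
ode_conc <- function(t, dose, p, rtol = 1e-10) {
  m <- micro_constants(p)
  two <- !is.null(m$k12)
  deriv <- function(tt, y, parms) {
    if (two) {
      list(c(-m$ka * y[1],
             m$ka * y[1] - (m$k10 + m$k12) * y[2] + m$k21 * y[3],
             m$k12 * y[2] - m$k21 * y[3]))
    } else {
      list(c(-m$ka * y[1], m$ka * y[1] - m$k10 * y[2]))
    }
  }
  u <- pmax(t - p$alag, 0)
  grid <- sort(unique(c(0, u)))
  y0 <- c(p$f_rel * dose, numeric(if (two) 2 else 1))
  out <- deSolve::ode(y0, grid, deriv, NULL, rtol = rtol, atol = 1e-13)
  stats::approx(out[, 1], out[, 3], xout = u)$y * 1000 / p$v2_f
}

# random plausible parameter sets for property-style tests
random_params <- function(two_cpt = TRUE) {
  p <- list(cl_f = exp(runif(1, log(1), log(30))),
            v2_f = exp(runif(1, log(20), log(400))),
            ka = exp(runif(1, log(0.2), log(3))),
            alag = runif(1, 0, 1.5))
  if (two_cpt) {
    p$q_f <- exp(runif(1, log(5), log(200)))
    p$v3_f <- exp(runif(1, log(30), log(500)))
  }
  do.call(structural_params, p)
}

# tiny noise-free trial design for pipeline-identity tests
tiny_trial_config <- function(n_child = 3) {
  cfg <- trial_config("lion")
  cfg$strata[[1]]$n_subjects <- n_child
  cfg$strata[[2]]$n_subjects <- 0
  cfg
}
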