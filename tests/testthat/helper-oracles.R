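# Independent oracles used across the test suite. These deliberately do
# not reuse the package's closed-form or estimation code paths.

# Two-compartment infusion concentrations by adaptive ODE integration.
ode_conc <- function(params, regimen, times) {
  rhs <- function(t, A, parms) {
    R <- 0
    for (d in seq_len(nrow(regimen))) {
      if (t > regimen$start_time[d] &&
          t <= regimen$start_time[d] + regimen$duration[d]) {
        R <- R + regimen$rate[d]
      }
    }
    k10 <- params$CL / params$V1
    k12 <- params$Q / params$V1
    k21 <- params$Q / params$V2
    list(c(R - (k10 + k12) * A[1] + k21 * A[2],
           k12 * A[1] - k21 * A[2]))
  }
  tt <- sort(unique(c(0, times, regimen$start_time,
                      regimen$start_time + regimen$duration)))
  sol <- deSolve::ode(c(0, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  conc <- sol[, 2] / params$V1
  conc[match(times, tt)]
}

# One-subject exact marginal -2 log-likelihood with a single active
# random effect, by adaptive Gauss-Hermite quadrature (centred and scaled
# at the conditional mode).
ghq_subject_neg2ll <- function(data, theta, omega2, sigma, active,
                               n_nodes = 21) {
  gh <- pracma::gaussHermite(n_nodes)
  obs <- data[data$evid == 0 & data$mdv == 0, ]
  dose <- data[data$evid == 1, ]
  reg <- tibble::tibble(start_time = dose$time, amount = dose$amt,
                        duration = dose$amt / dose$rate,
                        rate = dose$rate)
  omega <- sqrt(omega2[active])
  dens_y <- function(eta) {
    p <- as_theta_vec(theta)
    p[active] <- p[active] * exp(eta)
    pr <- conc_profile(pk_params(p[1], p[2], p[3], p[4]), reg,
                       obs$time)$conc
    prod(stats::dnorm(obs$dv, mean = pr, sd = sigma * pr))
  }
  # crude mode/curvature scan for the adaptive centre
  grid <- seq(-4 * omega, 4 * omega, length.out = 161)
  lp <- vapply(grid, function(e) {
    log(dens_y(e)) + stats::dnorm(e, 0, omega, log = TRUE)
  }, numeric(1))
  i0 <- which.max(lp)
  mu <- grid[i0]
  h <- grid[2] - grid[1]
  i1 <- min(max(i0, 2), length(grid) - 1)
  curv <- -(lp[i1 - 1] - 2 * lp[i1] + lp[i1 + 1]) / h^2
  tau <- if (is.finite(curv) && curv > 0) 1 / sqrt(curv) else omega
  nodes <- mu + sqrt(2) * tau * gh$x
  w <- gh$w
  integrand <- vapply(nodes, function(e) {
    dens_y(e) * stats::dnorm(e, 0, omega)
  }, numeric(1))
  lik <- sqrt(2) * tau * sum(w * exp(gh$x^2) * integrand)
  -2 * log(lik)
}

as_theta_vec <- function(theta) {
  if (inherits(theta, "pk_params")) theta <- unlist(theta)
  as.numeric(theta)
}

# Direct density-product conditional objective for a toy subject
# (hand-coded, independent of the package machinery).
direct_neg2ll <- function(obs_times, obs_dv, regimen, theta, omega2,
                          sigma, eta_full) {
  p <- as_theta_vec(theta) * exp(eta_full)
  pr <- conc_profile(pk_params(p[1], p[2], p[3], p[4]), regimen,
                     obs_times)$conc
  act <- which(omega2 > 0)
  -2 * (sum(stats::dnorm(obs_dv, pr, sigma * pr, log = TRUE)) +
          sum(stats::dnorm(eta_full[act], 0, sqrt(omega2[act]),
                           log = TRUE)))
}

# Random valid parameter sets for property checks.
random_params <- function() {
  pk_params(CL = stats::runif(1, 0.5, 10), V1 = stats::runif(1, 5, 60),
            V2 = stats::runif(1, 5, 80), Q = stats::runif(1, 1, 25))
}

make_scenario_data <- function(type = "PK3", CL = 4.5, dur = 1, n = 5,
                               seed = 1, omega = 0.3, sigma = 0.1) {
  simulate_dataset(scenario_spec(type, CL, dur, n),
                   variance_spec(omega, sigma), seed = seed)
}
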