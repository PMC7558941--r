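# Closed-form two-compartment infusion model.

test_that("macro constants match hand-derived micro-rate constants", {
  mc <- macro_constants(vanco_params(CL = 1.5))
  expect_equal(mc$k10, 1.5 / 24.2, tolerance = 1e-12)
  expect_equal(mc$k10, 0.061983, tolerance = 1e-4)
  expect_equal(mc$k12, 11.2 / 24.2, tolerance = 1e-12)
  expect_equal(mc$k21, 11.2 / 32.3, tolerance = 1e-12)
  expect_equal(mc$k21, 0.346749, tolerance = 1e-4)
})

test_that("disposition roots satisfy the quadratic identities", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_params()
    mc <- macro_constants(p)
    expect_gt(mc$alpha, mc$beta)
    expect_gt(mc$beta, 0)
    expect_equal(mc$alpha + mc$beta, mc$k10 + mc$k12 + mc$k21,
                 tolerance = 1e-12)
    expect_equal(mc$alpha * mc$beta, mc$k10 * mc$k21, tolerance = 1e-12)
    expect_gte(mc$A, 0)
    expect_gte(mc$B, 0)
    expect_equal(mc$A + mc$B, 1 / p$V1, tolerance = 1e-12)
  }
})

test_that("invalid parameters are rejected", {
  expect_error(pk_params(CL = -1, V1 = 24.2, V2 = 32.3, Q = 11.2),
               "positive")
  expect_error(pk_params(CL = 1.5, V1 = 0, V2 = 32.3, Q = 11.2),
               "positive")
  expect_error(macro_constants(pk_params(1.5, 24.2, 32.3, 0)), "Q > 0")
  expect_error(dose_event(0, 0, 1), "> 0")
  expect_error(dose_event(0, 1000, 0), "> 0")
  expect_error(regimen(dose_event(0, 1000, 1), dose_event(0, 500, 1)),
               "strictly increasing")
})

test_that("single-dose concentration starts at zero and rises during infusion", {
  p <- vanco_params(1.5)
  dose <- dose_event(0, 1000, 1)
  expect_identical(conc_single_dose(p, dose, 0), 0)
  tt <- seq(0, 1, by = 0.02)
  cc <- conc_single_dose(p, dose, tt)
  expect_true(all(diff(cc) > 0))
  expect_true(all(cc >= 0))
  expect_error(conc_single_dose(p, dose, -0.5), ">= 0")
})

test_that("during/post-infusion branches are continuous at the end of infusion", {
  set.seed(21)
  for (i in 1:20) {
    p <- random_params()
    tinf <- sample(c(0.5, 1, 2, 4), 1)
    dose <- dose_event(0, 1000, tinf)
    eps <- 1e-9
    lo <- conc_single_dose(p, dose, tinf - eps)
    hi <- conc_single_dose(p, dose, tinf + eps)
    at <- conc_single_dose(p, dose, tinf)
    expect_lt(abs(hi - lo), 1e-6 * at)
  }
})

test_that("closed form agrees with adaptive ODE integration", {
  # randomized parameter/regimen/time triples against the oracle
  set.seed(42)
  for (i in 1:40) {
    p <- random_params()
    n_doses <- sample(1:4, 1)
    tinf <- sample(c(1, 2, 4), 1)
    reg <- regimen(purrr::map(seq_len(n_doses) - 1,
                              ~ dose_event(12 * .x, 1000, tinf)))
    times <- sort(stats::runif(5, 0.1, 12 * n_doses + 6))
    expect_equal(conc_profile(p, reg, times)$conc,
                 ode_conc(p, reg, times), tolerance = 1e-6)
  }
})

test_that("multiple-dose profile is the superposition of shifted single doses", {
  p <- vanco_params(4.5)
  reg <- q12h_regimen(4, 1000, 1)
  times <- c(0.5, 3, 13, 25, 37, 47.9)
  manual <- rowSums(vapply(seq_len(4), function(d) {
    ifelse(times > reg$start_time[d],
           conc_single_dose(p, dose_event(0, 1000, 1),
                            pmax(times - reg$start_time[d], 0)), 0)
  }, numeric(length(times))))
  expect_equal(conc_profile(p, reg, times)$conc, manual, tolerance = 1e-12)
  one <- regimen(dose_event(0, 1000, 2))
  expect_equal(conc_profile(p, one, times)$conc,
               conc_single_dose(p, dose_event(0, 1000, 2), times),
               tolerance = 1e-12)
})

test_that("concentration is homogeneous of degree one in dose amount", {
  p <- vanco_params(1.5)
  times <- seq(0.5, 47.5, by = 3)
  base <- conc_profile(p, q12h_regimen(4, 1000, 2), times)$conc
  doubled <- conc_profile(p, q12h_regimen(4, 2000, 2), times)$conc
  expect_equal(doubled, 2 * base, tolerance = 1e-12)
})

test_that("steady-state infusion concentration equals rate/CL and the macro identity", {
  p <- vanco_params(1.5)
  expect_equal(steady_state_infusion_conc(p, 1000), 1000 / 1.5,
               tolerance = 1e-12)
  mc <- macro_constants(p)
  expect_equal(1000 * (mc$A / mc$alpha + mc$B / mc$beta), 1000 / p$CL,
               tolerance = 1e-10)
  expect_error(steady_state_infusion_conc(p, 0), "> 0")
  # the during-infusion equation approaches rate/CL for large t
  far <- conc_single_dose(p, dose_event(1e6 * 1000, 1000 * 1e6, 1e6), 5e5)
  expect_equal(far, 1000 / 1.5, tolerance = 1e-6)
})

test_that("Q = 0 selects the one-compartment limit", {
  p <- pk_params(CL = 2, V1 = 30, V2 = 32.3, Q = 0)
  dose <- dose_event(0, 1000, 1)
  ke <- 2 / 30
  tt <- c(0.25, 0.75, 1, 2, 6)
  expected <- ifelse(tt <= 1,
                     1000 / 2 * (1 - exp(-ke * tt)),
                     1000 / 2 * (1 - exp(-ke)) * exp(-ke * (tt - 1)))
  expect_equal(conc_single_dose(p, dose, tt), expected, tolerance = 1e-12)
})
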