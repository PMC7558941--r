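# Nonlinear mixed-effects estimation machinery.

toy_subject <- function(eta = c(0.1, -0.2, 0.05, 0.15), sigma = 0.1,
                        seed = 31, id = 1L) {
  # one subject, one 1-h infusion, two observations
  set.seed(seed)
  p <- unlist(vanco_params(1.5)) * exp(eta)
  reg <- regimen(dose_event(0, 1000, 1))
  tt <- c(2, 8)
  pr <- conc_profile(pk_params(p[1], p[2], p[3], p[4]), reg, tt)$conc
  dv <- pr * (1 + sigma * stats::rnorm(2))
  tibble::tibble(
    id = id,
    time = c(0, tt),
    amt = c(1000, NA, NA), rate = c(1000, NA, NA),
    evid = c(1L, 0L, 0L), mdv = c(1L, 0L, 0L),
    dv = c(NA, dv)
  )
}

test_that("subject conditional objective matches a direct density product", {
  d <- toy_subject()
  eta <- c(0.1, -0.2, 0.05, 0.15)
  omega2 <- rep(0.09, 4)
  got <- subject_neg2ll(d, vanco_params(1.5), omega2, 0.1, eta)
  obs <- usable_obs(d)
  want <- direct_neg2ll(obs$time, obs$dv, regimen(dose_event(0, 1000, 1)),
                        vanco_params(1.5), omega2, 0.1, eta)
  expect_equal(got, want, tolerance = 1e-10)
  # one active effect only
  got1 <- subject_neg2ll(d, vanco_params(1.5), c(0.09, 0, 0, 0), 0.1, 0.1)
  want1 <- direct_neg2ll(obs$time, obs$dv, regimen(dose_event(0, 1000, 1)),
                         vanco_params(1.5), c(0.09, 0, 0, 0), 0.1,
                         c(0.1, 0, 0, 0))
  expect_equal(got1, want1, tolerance = 1e-10)
  expect_error(subject_neg2ll(d, vanco_params(1.5), omega2, 0.1, c(0, 0)),
               "length")
})

test_that("conditional modes shrink to zero as omega2 -> 0 and recover true eta when noise vanishes", {
  d <- make_scenario_data("PK3", CL = 1.5, n = 2, seed = 7)
  tiny <- conditional_modes(d, vanco_params(1.5), rep(1e-10, 4), 0.1)
  expect_lt(max(abs(as.matrix(tiny[, 2:5]))), 1e-6)

  # near-noise-free subject: the mode approaches the simulating eta
  eta_true <- c(0.2, -0.1, 0.15, -0.25)
  d2 <- toy_subject(eta = eta_true, sigma = 0)
  d2$dv[d2$evid == 0] <- d2$dv[d2$evid == 0] # exact predictions
  # add more observations for 4-effect identifiability
  p <- unlist(vanco_params(1.5)) * exp(eta_true)
  tt <- c(0.5, 1, 2, 4, 8, 12, 24)
  pr <- conc_profile(pk_params(p[1], p[2], p[3], p[4]),
                     regimen(dose_event(0, 1000, 1)), tt)$conc
  d3 <- tibble::tibble(
    id = 1L, time = c(0, tt), amt = c(1000, rep(NA, 7)),
    rate = c(1000, rep(NA, 7)), evid = c(1L, rep(0L, 7)),
    mdv = c(1L, rep(0L, 7)), dv = c(NA, pr)
  )
  m <- conditional_modes(d3, vanco_params(1.5), rep(0.09, 4), 1e-4)
  expect_equal(unlist(m[1, 2:5]), eta_true, tolerance = 1e-3,
               ignore_attr = TRUE)

  # duplicated subject gets an identical mode
  d4 <- dplyr::bind_rows(d3, dplyr::mutate(d3, id = 2L))
  m4 <- conditional_modes(d4, vanco_params(1.5), rep(0.09, 4), 0.1)
  expect_equal(unlist(m4[1, 2:5]), unlist(m4[2, 2:5]), tolerance = 1e-10)
})

test_that("marginal objective is invariant to subject order and matches between compiled and pure-R paths", {
  d <- make_scenario_data("PK1", CL = 4.5, n = 4, seed = 13)
  th <- vanco_params(4.5)
  o1 <- marginal_objective(d, th, rep(0.09, 4), 0.1)
  perm <- dplyr::arrange(d, dplyr::desc(.data$id), .data$time, .data$evid)
  o2 <- marginal_objective(perm, th, rep(0.09, 4), 0.1)
  expect_equal(o1, o2, tolerance = 1e-10)
  for (m in c("focei", "laplace")) {
    oc <- marginal_objective(d, th, rep(0.09, 4), 0.1, method = m)
    or <- marginal_objective(d, th, rep(0.09, 4), 0.1, method = m,
                             settings = estimation_settings(
                               method = m, compiled = FALSE))
    expect_equal(oc, or, tolerance = 1e-8)
  }
})

test_that("conditional objectives agree with adaptive Gauss-Hermite quadrature on one-random-effect instances", {
  # single active random effect on CL; quadrature is the exact marginal
  omega2 <- c(0.09, 0, 0, 0)
  for (seed in c(3, 17)) {
    d <- simulate_dataset(scenario_spec("PK1", 1.5, 1, 3),
                          variance_spec(omega = c(0.3, 0, 0, 0),
                                        sigma = 0.1), seed = seed)
    th <- vanco_params(1.5)
    exact <- sum(vapply(1:3, function(i) {
      ghq_subject_neg2ll(d[d$id == i, ], th, omega2, 0.1, active = 1)
    }, numeric(1)))
    lap <- marginal_objective(d, th, omega2, 0.1, method = "laplace")
    foc <- marginal_objective(d, th, omega2, 0.1, method = "focei")
    expect_lt(abs(lap - exact), 0.5)
    expect_lt(abs(foc - exact), 0.5)
  }
})

test_that("the importance-sampling likelihood check agrees with quadrature", {
  # the adjudicator used for suspicious fits, against the exact marginal
  d <- simulate_dataset(scenario_spec("PK1", 1.5, 1, 3),
                        variance_spec(omega = c(0.3, 0, 0, 0),
                                      sigma = 0.1), seed = 5)
  th <- vanco_params(1.5)
  omega2 <- c(0.09, 0, 0, 0)
  exact <- sum(vapply(1:3, function(i) {
    ghq_subject_neg2ll(d[d$id == i, ], th, omega2, 0.1, active = 1)
  }, numeric(1)))
  is_est <- popsse:::is_neg2ll_prepared(popsse:::prepare_fit_data(d),
                                        popsse:::as_theta(th), omega2, 0.1)
  expect_lt(abs(is_est - exact), 1)
})

test_that("noise-free data identifies the structural parameters", {
  sc <- scenario_spec("PK3", CL = 4.5, infusion_duration = 1, n_subjects = 8)
  d <- simulate_dataset(sc, variance_spec(omega = 0, sigma = 1e-6),
                        seed = 19)
  f <- fit_ppk(d, init = list(theta = unlist(vanco_params(4.5)) * 1.15,
                              omega2 = rep(1e-6, 4), sigma = 1e-6))
  expect_equal(unname(f$theta), c(4.5, 24.2, 32.3, 11.2),
               tolerance = 1e-3)
  expect_lt(f$sigma, 1e-4)
})

test_that("fitting is deterministic", {
  d <- make_scenario_data("PK1", CL = 4.5, n = 6, seed = 23)
  init <- list(theta = vanco_params(4.5), omega2 = rep(0.09, 4),
               sigma = 0.1)
  f1 <- fit_ppk(d, init = init)
  f2 <- fit_ppk(d, init = init)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$eta_modes, f2$eta_modes)
})

test_that("rescaling the concentration unit rescales volumes and clearances but not sigma", {
  d <- make_scenario_data("PK3", CL = 4.5, n = 8, seed = 29)
  init <- list(theta = vanco_params(4.5), omega2 = rep(0.09, 4),
               sigma = 0.1)
  f1 <- fit_ppk(d, init = init)
  c0 <- 2
  d2 <- dplyr::mutate(d, dv = .data$dv * c0)
  init2 <- list(theta = unlist(vanco_params(4.5)) / c0,
                omega2 = rep(0.09, 4), sigma = 0.1)
  f2 <- fit_ppk(d2, init = init2)
  expect_equal(unname(f2$theta), unname(f1$theta) / c0, tolerance = 1e-4)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-4)
  expect_equal(unname(f2$omega2), unname(f1$omega2), tolerance = 1e-3)
})

test_that("fit results carry tidy() and glance() methods", {
  d <- make_scenario_data("PK1", CL = 4.5, n = 5, seed = 37)
  f <- fit_ppk(d, init = list(theta = vanco_params(4.5),
                              omega2 = rep(0.09, 4), sigma = 0.1))
  td <- tidy(f)
  expect_equal(td$term[1:4], c("CL", "V1", "V2", "Q"))
  expect_equal(nrow(td), 9)
  expect_true(all(td$estimate > 0))
  gl <- glance(f)
  expect_equal(gl$n_subjects, 5)
  expect_equal(gl$n_obs, 20)
  expect_true(is.finite(gl$objective))
})

test_that("degenerate inputs are rejected", {
  d <- make_scenario_data("PK1", CL = 4.5, n = 3, seed = 41)
  expect_error(fit_ppk(d[d$id == 1, ],
                       init = list(theta = vanco_params(4.5),
                                   omega2 = rep(0.09, 4), sigma = 0.1)),
               "2 subjects")
  no_obs <- d
  no_obs$mdv[no_obs$id == 2] <- 1L
  expect_error(popsse:::prepare_fit_data(no_obs), "no usable")
})
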