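# Virtual cohort simulation and NONMEM-dialect I/O.

test_that("sampling schedules are the fixed per-duration offsets", {
  expect_equal(sampling_offsets(1), c(0, 1, 2, 4, 12))
  expect_equal(sampling_offsets(2), c(0, 2, 3, 5, 12))
  expect_equal(sampling_offsets(4), c(0, 4, 5, 9, 12))
  expect_error(sampling_offsets(3), "no sampling schedule")
})

test_that("scenario grid is the 72-cell cross product with unique rows", {
  g <- scenario_grid()
  expect_equal(nrow(g), 72)
  expect_equal(nrow(dplyr::distinct(g)), 72)
  expect_equal(nrow(dplyr::filter(g, .data$infusion_duration == 1)), 24)
  expect_setequal(unique(g$dataset_type), c("PK1", "PK2", "PK3"))
  expect_setequal(unique(g$n_subjects), c(25L, 50L, 100L, 200L))
})

test_that("exponential BSV draws have the lognormal mean and log-scale SD", {
  pop <- vanco_params(1.5)
  vs <- variance_spec()
  expect_equal(unname(vs$omega), rep(0.30, 4))
  expect_equal(vs$sigma, 0.10)
  set.seed(99)
  zero <- draw_individual(pop, variance_spec(omega = 0, sigma = 0))
  expect_equal(unlist(zero), unlist(pop), tolerance = 1e-15)
  set.seed(123)
  cls <- replicate(1e5, stats::rnorm(1)) # placeholder stream shape
  set.seed(123)
  draws <- vapply(seq_len(1e5), function(i) draw_individual(pop, vs)$CL,
                  numeric(1))
  expect_equal(mean(draws), 1.5 * exp(0.3^2 / 2), tolerance = 0.01)
  expect_equal(stats::sd(log(draws)), 0.30, tolerance = 0.02)
})

test_that("noise-free simulation reproduces the model profile exactly", {
  sc <- scenario_spec("PK3", CL = 1.5, infusion_duration = 2, n_subjects = 3)
  d <- simulate_dataset(sc, variance_spec(omega = 0, sigma = 0), seed = 4)
  obs <- usable_obs(d)
  expected <- conc_profile(vanco_params(1.5), q12h_regimen(4, 1000, 2),
                           obs$time[obs$id == 1])$conc
  for (i in 1:3) {
    expect_equal(obs$dv[obs$id == i], expected, tolerance = 1e-12)
  }
})

test_that("dataset structure follows the sampling-period design", {
  sc <- scenario_spec("PK3", CL = 4.5, infusion_duration = 1, n_subjects = 4)
  d <- simulate_dataset(sc, seed = 10)
  # 9 usable observations per subject: 4 post-first-dose (0 h excluded),
  # 5 around the fourth dose
  expect_equal(nrow(usable_obs(d)), 4 * 9)
  first0 <- dplyr::filter(d, .data$evid == 0, .data$time == 0)
  expect_true(all(first0$mdv == 1))
  # fourth-dose sampling times for 1-h infusions
  pk2 <- simulate_dataset(scenario_spec("PK2", 4.5, 1, 2), seed = 10)
  expect_equal(sort(unique(usable_obs(pk2)$time)), c(36, 37, 38, 40, 48))
  # doses at 0, 12, 24, 36 with observation-before-dose at coincident times
  doses <- dplyr::filter(d, .data$id == 1, .data$evid == 1)
  expect_equal(doses$time, c(0, 12, 24, 36))
  rows36 <- which(d$id == 1 & d$time == 36)
  expect_equal(d$evid[rows36], c(0L, 1L))
  expect_true(all(usable_obs(d)$dv >= 0))
})

test_that("simulation is reproducible and subject streams are prefix-stable", {
  sc <- scenario_spec("PK1", CL = 1.5, infusion_duration = 1, n_subjects = 6)
  d1 <- simulate_dataset(sc, seed = 5)
  d2 <- simulate_dataset(sc, seed = 5)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_dataset(sc, seed = 6)
  expect_false(identical(d1$dv, d3$dv))
  big <- simulate_dataset(scenario_spec("PK1", 1.5, 1, 20), seed = 5)
  expect_equal(as.data.frame(dplyr::filter(big, .data$id <= 6)),
               as.data.frame(d1), ignore_attr = TRUE)
})

test_that("accumulation raises the 48-h trough above the 12-h trough", {
  sc <- scenario_spec("PK3", CL = 1.5, infusion_duration = 1,
                      n_subjects = 1000)
  d <- usable_obs(simulate_dataset(sc, seed = 3))
  t12 <- d$dv[d$time == 12]
  t48 <- d$dv[d$time == 48]
  expect_gt(mean(t48), mean(t12))
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(stats::quantile(t48, qs) > stats::quantile(t12, qs)))
})

test_that("NONMEM-dialect CSV round trip is lossless", {
  sc <- scenario_spec("PK3", CL = 4.5, infusion_duration = 1,
                      n_subjects = 25)
  d <- simulate_dataset(sc, seed = 8)
  expect_equal(nrow(d), 25 * (4 + 10))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  header <- readLines(f, n = 2)
  expect_equal(header[1], "ID,TIME,AMT,RATE,EVID,MDV,DV")
  expect_match(header[2], "\\.")
  back <- read_dataset(f)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("malformed dataset files raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,EVID,MDV,DV",
               "1,0,1000,1000,1,1,.",
               "1,abc,.,.,0,0,12.3"), f)
  expect_error(suppressWarnings(read_dataset(f)), "line")
})
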