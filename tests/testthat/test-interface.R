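# Configuration, dataset export, pipeline drivers and figures.

stub_truth <- function(data, init) {
  list(theta = init$theta, omega2 = init$omega2, sigma = init$sigma,
       converged = TRUE)
}

test_that("configurations validate filters and round-trip through YAML", {
  cfg <- run_config(dataset_types = "PK1", CL = 1.5,
                    infusion_durations = 1, n_subjects = c(25, 50),
                    replicates = 2, seed = 7)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(run_config(dataset_types = character(0)), "empty")
  expect_error(run_config(infusion_durations = 3), "no sampling schedule")
  expect_error(run_config(dataset_types = "PK9"))
})

test_that("config_scenarios builds the filtered cross product", {
  cfg <- run_config(dataset_types = "PK1", replicates = 1)
  sc <- config_scenarios(cfg)
  expect_equal(nrow(sc), 24) # 2 CL x 3 durations x 4 sample sizes
  expect_true(all(sc$dataset_type == "PK1"))
  expect_true(all(sc$canonical))
})

test_that("sse_simulate writes one named file per scenario replicate with a stable manifest", {
  out1 <- withr::local_tempdir()
  cfg <- run_config(dataset_types = "PK1", CL = c(1.5, 4.5),
                    infusion_durations = 1, n_subjects = c(25, 50),
                    replicates = 2, seed = 3, output_dir = out1)
  man1 <- sse_simulate(cfg, quiet = TRUE)
  expect_equal(nrow(man1), 4 * 2)
  expect_true(all(file.exists(file.path(out1, man1$file))))
  expect_true("PK1_1.5_1h_n25_rep1.csv" %in% man1$file)
  expect_true(file.exists(file.path(out1, "manifest.csv")))
  expect_true(file.exists(file.path(out1, "config.yaml")))
  # a rerun with the same seed reproduces identical file hashes
  out2 <- withr::local_tempdir()
  cfg2 <- run_config(dataset_types = "PK1", CL = c(1.5, 4.5),
                     infusion_durations = 1, n_subjects = c(25, 50),
                     replicates = 2, seed = 3, output_dir = out2)
  man2 <- sse_simulate(cfg2, quiet = TRUE)
  expect_equal(man1$md5, man2$md5)
  # datasets on disk are readable and match a direct simulation
  d <- read_dataset(file.path(out1, "PK1_1.5_1h_n25_rep1.csv"))
  expect_equal(length(unique(d$id)), 25)
})

test_that("sse_run writes summaries, estimates, config and figures", {
  out <- withr::local_tempdir()
  cfg <- run_config(dataset_types = c("PK1", "PK3"), CL = 1.5,
                    infusion_durations = 1, n_subjects = 25,
                    replicates = 2, seed = 5, output_dir = out)
  s <- sse_run(cfg, fit_fn = stub_truth, quiet = TRUE)
  expect_true(all(s$rbias == 0)) # truth stub: all-zero panels
  for (fn in c("summary.csv", "estimates.csv", "config.yaml",
               "rbias.png", "rrmse.png")) {
    expect_true(file.exists(file.path(out, fn)))
  }
  back <- readr::read_csv(file.path(out, "summary.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$rbias, s$rbias)
})

test_that("summary plots and the loading-dose illustration are ggplot objects", {
  sc <- scenario_spec("PK1", 1.5, 1, 5)
  s <- run_sse(sc, n_replicates = 2, base_seed = 1, fit_fn = stub_truth)
  expect_s3_class(autoplot(s, metric = "rbias"), "ggplot")
  expect_s3_class(autoplot(s, metric = "rrmse", terms = "structural"),
                  "ggplot")
  expect_s3_class(plot_loading_dose(), "ggplot")
})

test_that("the command-line entry point ships with the package", {
  cli <- system.file("cli", "popsse.R", package = "popsse")
  expect_true(nzchar(cli))
  expect_true(file.exists(cli))
})
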