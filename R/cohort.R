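# Virtual cohort simulation: scenario grid, between-subject variability,
# residual error, and NONMEM-dialect dataset I/O.

CANONICAL_CL <- c(1.5, 4.5)
CANONICAL_DURATIONS <- c(1, 2, 4)
CANONICAL_N <- c(25, 50, 100, 200)
DATASET_TYPES <- c("PK1", "PK2", "PK3")
PARAM_NAMES <- c("CL", "V1", "V2", "Q")

#' Between-subject and residual variability specification
#'
#' Between-subject variability (BSV) is exponential on each structural
#' parameter, `theta_i = theta * exp(eta_i)` with `eta_i ~ N(0, omega^2)`;
#' residual variability (RV) is proportional,
#' `y_ij = yhat_ij * (1 + sigma * eps_ij)` with `eps_ij ~ N(0, 1)`.
#' The study conditions set a 30% CV on all four structural parameters
#' (`omega = 0.30`, so `omega^2 = 0.09`) and a 10% proportional error
#' coefficient (`sigma = 0.10`, an SD-scale quantity).
#'
#' @param omega BSV standard deviations on the log scale; a scalar (recycled
#'   to all four parameters) or a length-4 vector ordered CL, V1, V2, Q.
#'   Zero disables the random effect on that parameter.
#' @param sigma Proportional residual error coefficient (SD scale).
#' @return A `variance_spec` object: list with `omega` (named length-4
#'   vector) and `sigma`.
#' @examples
#' variance_spec()                     # the default study conditions
#' variance_spec(omega = 0, sigma = 0) # noise-free simulation
#' @export
variance_spec <- function(omega = 0.30, sigma = 0.10) {
  if (length(omega) == 1) omega <- rep(omega, 4)
  stopifnot(length(omega) == 4, all(omega >= 0), length(sigma) == 1,
            sigma >= 0)
  structure(list(omega = stats::setNames(as.numeric(omega), PARAM_NAMES),
                 sigma = as.numeric(sigma)),
            class = "variance_spec")
}

#' Blood-sampling schedule for a given infusion duration
#'
#' Fixed sampling offsets (h from the start of a dose): pre-dose (0 h) plus
#' four post-start times, chosen per infusion duration so that samples
#' bracket the end of the infusion and the end of the dosing interval.
#'
#' @param infusion_duration Infusion duration in h; one of 1, 2 or 4
#'   (the schedules are fixed by design; no interpolation is invented).
#' @return Numeric vector of five offsets (h).
#' @examples
#' sampling_offsets(1) # 0, 1, 2, 4, 12
#' @export
sampling_offsets <- function(infusion_duration) {
  switch(as.character(infusion_duration),
    "1" = c(0, 1, 2, 4, 12),
    "2" = c(0, 2, 3, 5, 12),
    "4" = c(0, 4, 5, 9, 12),
    stop("no sampling schedule defined for infusion duration ",
         infusion_duration, " h", call. = FALSE)
  )
}

#' Scenario specification and the full scenario grid
#'
#' A scenario is one cell of the study design: which sampling period the
#' dataset covers (`PK1` first dose, `PK2` fourth dose, `PK3` both), the
#' true total clearance, the infusion duration and the cohort size.
#' `scenario_grid()` returns the full cross product
#' 3 dataset types x 2 clearances x 3 infusion durations x 4 sample
#' sizes = 72 scenarios.
#'
#' @param dataset_type One of `"PK1"`, `"PK2"`, `"PK3"`.
#' @param CL True total clearance (L/h); canonical values 1.5 and 4.5.
#' @param infusion_duration Infusion duration (h); canonical 1, 2, 4.
#' @param n_subjects Cohort size; canonical 25, 50, 100, 200.
#' @return A one-row tibble (or, for `scenario_grid()`, a 72-row tibble)
#'   with those four columns plus `canonical`, flagging values drawn from
#'   the stated grids.
#' @examples
#' scenario_spec("PK3", CL = 4.5, infusion_duration = 1, n_subjects = 100)
#' nrow(scenario_grid())
#' @export
scenario_spec <- function(dataset_type, CL, infusion_duration, n_subjects) {
  dataset_type <- match.arg(dataset_type, DATASET_TYPES)
  stopifnot(CL > 0, infusion_duration > 0, n_subjects >= 1)
  tibble::tibble(
    dataset_type = dataset_type,
    CL = CL,
    infusion_duration = infusion_duration,
    n_subjects = as.integer(n_subjects),
    canonical = CL %in% CANONICAL_CL &&
      infusion_duration %in% CANONICAL_DURATIONS &&
      n_subjects %in% CANONICAL_N
  )
}

#' @rdname scenario_spec
#' @export
scenario_grid <- function() {
  tidyr::expand_grid(
    dataset_type = DATASET_TYPES,
    CL = CANONICAL_CL,
    infusion_duration = CANONICAL_DURATIONS,
    n_subjects = as.integer(CANONICAL_N)
  ) |>
    dplyr::mutate(canonical = TRUE)
}

# Deterministic substream derivation: fold integer components into a
# 31-bit seed with a Lehmer-style mix, so every (scenario, replicate,
# subject) stream is reproducible in isolation. All arithmetic stays
# exact in doubles (< 2^53).
derive_seed <- function(...) {
  parts <- c(...)
  s <- 1
  for (x in parts) {
    s <- (s * 48271 + (abs(x) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(s)
}

# The key feeds replicate-seed derivation and deliberately excludes the
# dataset type and cohort size: designs are then compared on matched
# virtual cohorts (PK1/PK2/PK3 share subjects at a given replicate, and a
# 25-subject cohort is a prefix of the 200-subject one), which pairs the
# Monte-Carlo noise in design contrasts.
scenario_key <- function(scenario) {
  derive_seed(round(scenario$CL * 1e3),
              round(scenario$infusion_duration * 1e3))
}

#' Draw individual parameters under exponential BSV
#'
#' Each structural parameter of one subject is the population typical value
#' multiplied by `exp(eta)`, `eta ~ N(0, omega^2)`, with independent draws
#' per parameter (diagonal covariance).
#'
#' @param pop Population typical values, a [pk_params] object.
#' @param var A [variance_spec()].
#' @return A [pk_params] object for one subject, drawn with the current RNG
#'   state.
#' @examples
#' set.seed(1)
#' draw_individual(vanco_params(1.5), variance_spec())
#' @export
draw_individual <- function(pop, var) {
  stopifnot(inherits(pop, "pk_params"), inherits(var, "variance_spec"))
  eta <- stats::rnorm(4, 0, var$omega)
  pk_params(CL = pop$CL * exp(eta[1]), V1 = pop$V1 * exp(eta[2]),
            V2 = pop$V2 * exp(eta[3]), Q = pop$Q * exp(eta[4]))
}

# Observation times (absolute h) for a scenario, with the mdv flag.
# The first-dose pre-dose sample has a model prediction of exactly zero,
# which makes the proportional error model degenerate there; it is emitted
# with mdv = 1 (excluded from fitting). The fourth-dose "0 h" sample is the
# 36-h trough, non-zero, and kept.
observation_schedule <- function(dataset_type, infusion_duration) {
  off <- sampling_offsets(infusion_duration)
  first <- tibble::tibble(time = off, mdv = as.integer(off == 0))
  fourth <- tibble::tibble(time = 36 + off, mdv = 0L)
  switch(dataset_type,
         PK1 = first,
         PK2 = fourth,
         PK3 = dplyr::bind_rows(first, fourth))
}

#' Simulate one scenario dataset
#'
#' Generates a cohort of `n_subjects` virtual subjects receiving 1000 mg
#' every 12 h (four doses), draws individual parameters under exponential
#' BSV, evaluates the closed-form two-compartment model at the scenario's
#' sampling schedule, and applies proportional residual error. Sampling
#' follows the first dose (`PK1`), the fourth dose starting at 36 h
#' (`PK2`), or both (`PK3`). Negative simulated concentrations (possible
#' since the error is unbounded) are truncated at zero.
#'
#' Subject-level random-number substreams are derived deterministically
#' from `seed`, so the first 25 subjects of a 200-subject cohort are
#' identical to the 25-subject cohort simulated with the same seed.
#'
#' @param scenario A one-row scenario tibble from [scenario_spec()].
#' @param var A [variance_spec()].
#' @param seed Integer seed for this dataset.
#' @param pop Population typical values; defaults to the reference
#'   vancomycin model with the scenario's clearance.
#' @param amount,interval,n_doses Dosing regimen (mg, h, count).
#' @return A `pop_dataset`: a tibble of NONMEM-dialect records with columns
#'   `id`, `time`, `amt`, `rate`, `evid`, `mdv`, `dv`, carrying the
#'   scenario, seed and true individual parameters as attributes
#'   (`scenario`, `seed`, `true_params`).
#' @examples
#' sc <- scenario_spec("PK1", CL = 1.5, infusion_duration = 1, n_subjects = 5)
#' simulate_dataset(sc, variance_spec(), seed = 42)
#' @export
simulate_dataset <- function(scenario, var = variance_spec(), seed = 1,
                             pop = NULL, amount = 1000, interval = 12,
                             n_doses = 4) {
  stopifnot(inherits(var, "variance_spec"))
  if (is.null(pop)) pop <- vanco_params(CL = scenario$CL)
  dur <- scenario$infusion_duration
  n <- scenario$n_subjects
  doses <- q12h_regimen(n_doses = n_doses, amount = amount, duration = dur)
  doses$start_time <- (seq_len(n_doses) - 1) * interval
  sched <- observation_schedule(scenario$dataset_type, dur)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  # per-subject substreams
  etas <- matrix(0, n, 4)
  eps <- matrix(0, n, nrow(sched))
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    etas[i, ] <- stats::rnorm(4, 0, var$omega)
    eps[i, ] <- stats::rnorm(nrow(sched))
  }
  true_params <- tibble::tibble(
    id = seq_len(n),
    CL = pop$CL * exp(etas[, 1]), V1 = pop$V1 * exp(etas[, 2]),
    V2 = pop$V2 * exp(etas[, 3]), Q = pop$Q * exp(etas[, 4])
  )

  pred <- conc_kernel(true_params$CL, true_params$V1, true_params$V2,
                      true_params$Q, sched$time, doses)
  dv <- pmax(pred * (1 + var$sigma * eps), 0)

  obs_rows <- tidyr::expand_grid(id = seq_len(n), row = seq_len(nrow(sched))) |>
    dplyr::transmute(
      id = .data$id,
      time = sched$time[.data$row],
      amt = NA_real_, rate = NA_real_, evid = 0L,
      mdv = sched$mdv[.data$row],
      dv = dv[cbind(.data$id, .data$row)]
    )
  dose_rows <- tidyr::expand_grid(id = seq_len(n), d = seq_len(n_doses)) |>
    dplyr::transmute(
      id = .data$id,
      time = doses$start_time[.data$d],
      amt = doses$amount[.data$d], rate = doses$rate[.data$d],
      evid = 1L, mdv = 1L, dv = NA_real_
    )
  # observation-before-dose at coincident times (trough convention)
  records <- dplyr::bind_rows(
    dplyr::mutate(obs_rows, .ord = 0L),
    dplyr::mutate(dose_rows, .ord = 1L)
  ) |>
    dplyr::arrange(.data$id, .data$time, .data$.ord) |>
    dplyr::select(-".ord")

  structure(records,
            class = c("pop_dataset", class(tibble::tibble()))) |>
    set_dataset_attrs(scenario = scenario, seed = seed,
                      true_params = true_params)
}

set_dataset_attrs <- function(x, scenario, seed, true_params = NULL) {
  attr(x, "scenario") <- scenario
  attr(x, "seed") <- seed
  attr(x, "true_params") <- true_params
  x
}

#' Usable observation records
#'
#' Keep only rows that enter the likelihood: observation events
#' (`evid == 0`) whose dependent value is not flagged missing
#' (`mdv == 0`).
#'
#' @param data A `pop_dataset` or compatible tibble.
#' @return The filtered tibble.
#' @export
usable_obs <- function(data) {
  dplyr::filter(data, .data$evid == 0, .data$mdv == 0)
}

#' Read and write NONMEM-dialect datasets
#'
#' Datasets are exchanged as CSV with header
#' `ID,TIME,AMT,RATE,EVID,MDV,DV` and `"."` for empty cells; one file per
#' scenario replicate. The round trip is lossless for these columns.
#'
#' @param data A `pop_dataset` (or compatible tibble) to write.
#' @param path File path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `pop_dataset` tibble.
#' @examples
#' sc <- scenario_spec("PK1", 1.5, 1, 3)
#' d <- simulate_dataset(sc, seed = 7)
#' f <- tempfile(fileext = ".csv")
#' write_dataset(d, f)
#' all.equal(as.data.frame(read_dataset(f)), as.data.frame(d))
#' @export
write_dataset <- function(data, path) {
  out <- dplyr::transmute(
    data,
    ID = .data$id, TIME = .data$time, AMT = .data$amt, RATE = .data$rate,
    EVID = .data$evid, MDV = .data$mdv, DV = .data$dv
  )
  readr::write_csv(out, path, na = ".")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- readr::read_csv(path, na = ".", col_types = readr::cols(
    ID = readr::col_double(), TIME = readr::col_double(),
    AMT = readr::col_double(), RATE = readr::col_double(),
    EVID = readr::col_integer(), MDV = readr::col_integer(),
    DV = readr::col_double()
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed dataset ", path, ": parse failure at line(s) ",
         paste(unique(probs$row + 1L), collapse = ", "), call. = FALSE)
  }
  if (anyNA(raw$TIME) || anyNA(raw$ID)) {
    bad <- which(is.na(raw$TIME) | is.na(raw$ID)) + 1L
    stop("malformed dataset ", path, ": missing ID/TIME at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    id = as.integer(raw$ID), time = raw$TIME, amt = raw$AMT,
    rate = raw$RATE, evid = raw$EVID, mdv = raw$MDV, dv = raw$DV
  )
  structure(out, class = c("pop_dataset", class(tibble::tibble())))
}
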