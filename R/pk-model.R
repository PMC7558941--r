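# Closed-form two-compartment IV-infusion model with multiple-dose
# superposition. All quantities are in mg, L, h, mg/L.

#' Structural pharmacokinetic parameters
#'
#' Bundle the four structural parameters of a two-compartment disposition
#' model with first-order elimination from the central compartment:
#' total clearance `CL` (L/h), central volume `V1` (L), peripheral volume
#' `V2` (L) and intercompartmental clearance `Q` (L/h).
#'
#' @param CL Total clearance (L/h), strictly positive.
#' @param V1 Central volume of distribution (L), strictly positive.
#' @param V2 Peripheral volume of distribution (L), strictly positive.
#' @param Q Intercompartmental clearance (L/h). Strictly positive for the
#'   two-compartment model; `Q = 0` selects the one-compartment degenerate
#'   model in which `V2` is inert.
#'
#' @return An object of class `pk_params`: a named list with elements
#'   `CL`, `V1`, `V2`, `Q`.
#' @examples
#' pk_params(CL = 4.5, V1 = 24.2, V2 = 32.3, Q = 11.2)
#' @export
pk_params <- function(CL, V1, V2, Q) {
  vals <- c(CL = CL, V1 = V1, V2 = V2, Q = Q)
  if (anyNA(vals) || !is.numeric(vals)) {
    stop("PK parameters must be finite numbers", call. = FALSE)
  }
  if (CL <= 0 || V1 <= 0 || V2 <= 0) {
    stop("CL, V1 and V2 must be strictly positive", call. = FALSE)
  }
  if (Q < 0) {
    stop("Q must be non-negative (Q = 0 selects the one-compartment model)",
         call. = FALSE)
  }
  structure(list(CL = CL, V1 = V1, V2 = V2, Q = Q), class = "pk_params")
}

#' Reference vancomycin two-compartment parameters
#'
#' Typical values from a published model of vancomycin disposition in adults:
#' `V1 = 24.2` L, `V2 = 32.3` L, `Q = 11.2` L/h, with total clearance
#' supplied by the caller (the source model reports 2.83 L/h; the sampling
#' design study evaluates 1.5 and 4.5 L/h).
#'
#' @param CL Total clearance in L/h (default 2.83).
#' @return A [pk_params] object.
#' @examples
#' vanco_params(CL = 4.5)
#' @export
vanco_params <- function(CL = 2.83) {
  pk_params(CL = CL, V1 = 24.2, V2 = 32.3, Q = 11.2)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params>  CL =", x$CL, "L/h  V1 =", x$V1, "L  V2 =", x$V2,
      "L  Q =", x$Q, "L/h\n")
  invisible(x)
}

#' Macro constants of the two-compartment model
#'
#' Derive the micro-rate constants `k10 = CL/V1`, `k12 = Q/V1`,
#' `k21 = Q/V2` and the hybrid disposition constants
#' `alpha, beta = (s +/- sqrt(s^2 - 4 k10 k21)) / 2` with
#' `s = k10 + k12 + k21`, together with the disposition coefficients
#' `A = (alpha - k21) / (V1 (alpha - beta))` and
#' `B = (k21 - beta) / (V1 (alpha - beta))`.
#'
#' The identities `alpha + beta = k10 + k12 + k21`, `alpha * beta =
#' k10 * k21` and `A + B = 1/V1` hold exactly up to floating-point error.
#'
#' @param params A [pk_params] object with `Q > 0`.
#' @return A `macro_constants` object: named list with `k10`, `k12`, `k21`,
#'   `alpha`, `beta`, `A`, `B`.
#' @examples
#' macro_constants(vanco_params(CL = 1.5))
#' @export
macro_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  if (params$Q <= 0) {
    stop("macro constants require Q > 0; use the one-compartment path for Q = 0",
         call. = FALSE)
  }
  k10 <- params$CL / params$V1
  k12 <- params$Q / params$V1
  k21 <- params$Q / params$V2
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21 # = (k10 - k21)^2 + k12 * (...) >= 0
  root <- sqrt(disc)
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  if (!is.finite(root) || root <= .Machine$double.eps * s) {
    stop("degenerate repeated disposition root (alpha == beta)", call. = FALSE)
  }
  A <- (alpha - k21) / (params$V1 * (alpha - beta))
  B <- (k21 - beta) / (params$V1 * (alpha - beta))
  structure(
    list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta,
         A = A, B = B),
    class = "macro_constants"
  )
}

#' Infusion dose events and regimens
#'
#' A dose event is one constant-rate intravenous infusion: start time (h
#' from the time origin), amount (mg) and duration (h); the rate (mg/h) is
#' `amount / duration`. A regimen is a tibble of dose events ordered by
#' strictly increasing start time, which is how multiple-dose profiles are
#' expressed for superposition.
#'
#' @param start_time Start of the infusion (h), `>= 0`.
#' @param amount Dose amount (mg), `> 0`.
#' @param duration Infusion duration (h), `> 0`.
#' @return `dose_event()` returns a one-row tibble with columns
#'   `start_time`, `amount`, `duration`, `rate`; `regimen()` binds dose
#'   events into an ordered regimen tibble.
#' @examples
#' regimen(dose_event(0, 1000, 1), dose_event(12, 1000, 1))
#' q12h_regimen(n_doses = 4, duration = 2)
#' @export
dose_event <- function(start_time, amount, duration) {
  stopifnot(is.numeric(start_time), is.numeric(amount), is.numeric(duration))
  if (start_time < 0) stop("start_time must be >= 0", call. = FALSE)
  if (amount <= 0) stop("dose amount must be > 0", call. = FALSE)
  if (duration <= 0) stop("infusion duration must be > 0", call. = FALSE)
  tibble::tibble(
    start_time = start_time, amount = amount, duration = duration,
    rate = amount / duration
  )
}

#' @param ... For `regimen()`: dose events (or tibbles of them) to combine.
#' @rdname dose_event
#' @export
regimen <- function(...) {
  reg <- dplyr::bind_rows(...)
  required <- c("start_time", "amount", "duration", "rate")
  if (!all(required %in% names(reg)) || nrow(reg) == 0) {
    stop("a regimen needs at least one dose event", call. = FALSE)
  }
  if (is.unsorted(reg$start_time, strictly = TRUE)) {
    stop("dose start times must be strictly increasing", call. = FALSE)
  }
  reg
}

#' @param n_doses For `q12h_regimen()`: number of doses.
#' @rdname dose_event
#' @export
q12h_regimen <- function(n_doses = 4, amount = 1000, duration = 1) {
  regimen(purrr::map(seq_len(n_doses) - 1,
                     ~ dose_event(12 * .x, amount, duration)))
}

# Vectorised concentration kernel.
#
# CL, V1, V2, Q: length-n vectors of individual parameters (numeric, or
# complex for complex-step differentiation). times: length-m numeric vector
# of absolute times. doses: data frame with start_time, rate, duration.
# Returns an n x m matrix of central-compartment concentrations (mg/L).
# Subjects with Q == 0 are evaluated on the one-compartment limit.
conc_kernel <- function(CL, V1, V2, Q, times, doses) {
  n <- length(CL)
  m <- length(times)
  cplx <- is.complex(CL) || is.complex(V1) || is.complex(V2) || is.complex(Q)
  out <- matrix(if (cplx) 0 + 0i else 0, n, m)
  if (m == 0L || n == 0L) return(out)

  one_cpt <- Re(Q) == 0
  two <- !one_cpt

  if (any(two)) {
    k10 <- CL[two] / V1[two]
    k12 <- Q[two] / V1[two]
    k21 <- Q[two] / V2[two]
    s <- k10 + k12 + k21
    root <- sqrt(s^2 - 4 * k10 * k21)
    alpha <- (s + root) / 2
    beta <- (s - root) / 2
    Aa <- (alpha - k21) / (V1[two] * (alpha - beta)) / alpha # A / alpha
    Bb <- (k21 - beta) / (V1[two] * (alpha - beta)) / beta   # B / beta
  }
  if (any(one_cpt)) {
    ke <- CL[one_cpt] / V1[one_cpt]
    inv_cl <- 1 / CL[one_cpt]
  }

  for (d in seq_len(nrow(doses))) {
    te <- times - doses$start_time[d]
    R <- doses$rate[d]
    tau <- doses$duration[d]
    act <- te > 0
    if (!any(act)) next
    w <- act & te <= tau  # during this infusion
    p <- act & te > tau   # after it
    if (any(two)) {
      if (any(w)) {
        ea <- exp(-outer(alpha, te[w]))
        eb <- exp(-outer(beta, te[w]))
        out[two, w] <- out[two, w] + R * (Aa * (1 - ea) + Bb * (1 - eb))
      }
      if (any(p)) {
        tp <- te[p] - tau
        ea <- exp(-outer(alpha, tp))
        eb <- exp(-outer(beta, tp))
        out[two, p] <- out[two, p] +
          R * (Aa * (1 - exp(-alpha * tau)) * ea +
                 Bb * (1 - exp(-beta * tau)) * eb)
      }
    }
    if (any(one_cpt)) {
      if (any(w)) {
        out[one_cpt, w] <- out[one_cpt, w] +
          R * inv_cl * (1 - exp(-outer(ke, te[w])))
      }
      if (any(p)) {
        tp <- te[p] - tau
        out[one_cpt, p] <- out[one_cpt, p] +
          R * inv_cl * (1 - exp(-ke * tau)) * exp(-outer(ke, tp))
      }
    }
  }
  out
}

#' Concentration after a single intravenous infusion
#'
#' Closed-form central-compartment concentration of the two-compartment
#' model for one constant-rate infusion. During the infusion
#' (`0 <= t <= duration`),
#' `C(t) = R (A/alpha (1 - e^(-alpha t)) + B/beta (1 - e^(-beta t)))`;
#' after its end the two exponential terms decay from their end-of-infusion
#' values with the elapsed time `t - duration` as the exponential argument,
#' which makes the two branches continuous at the end of the infusion.
#'
#' @param params A [pk_params] object.
#' @param dose A single dose event (see [dose_event()]); its `start_time`
#'   is ignored here — `t` is time since the start of this infusion.
#' @param t Time since infusion start (h); vectorised, all values `>= 0`.
#' @return Numeric vector of concentrations (mg/L).
#' @examples
#' conc_single_dose(vanco_params(1.5), dose_event(0, 1000, 1), c(0.5, 1, 2, 12))
#' @export
conc_single_dose <- function(params, dose, t) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) stop("t must be >= 0 (time since infusion start)", call. = FALSE)
  doses <- dose
  doses$start_time <- 0
  drop(conc_kernel(params$CL, params$V1, params$V2, params$Q, t, doses))
}

#' Multiple-dose concentration profile by superposition
#'
#' The model is linear, so the concentration under a multiple-dose regimen
#' is the sum of time-shifted single-dose profiles; doses that have not yet
#' started contribute zero.
#'
#' @param params A [pk_params] object.
#' @param regimen A regimen tibble (see [regimen()]).
#' @param times Absolute times (h from first-dose origin), all `>= 0`.
#'   Evaluated in the order given; no reordering is performed.
#' @return A tibble with columns `time` (h) and `conc` (mg/L).
#' @examples
#' conc_profile(vanco_params(1.5), q12h_regimen(4), times = 0:48)
#' @export
conc_profile <- function(params, regimen, times) {
  stopifnot(inherits(params, "pk_params"))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  cc <- drop(conc_kernel(params$CL, params$V1, params$V2, params$Q,
                         times, regimen))
  tibble::tibble(time = times, conc = cc)
}

#' Steady-state concentration under continuous infusion
#'
#' For a constant-rate infusion continued to steady state the concentration
#' is `rate / CL`, the limit of the during-infusion equation as time grows;
#' equivalently `rate * (A/alpha + B/beta)`.
#'
#' @param params A [pk_params] object.
#' @param rate Infusion rate (mg/h), `> 0`.
#' @return Steady-state concentration (mg/L).
#' @examples
#' steady_state_infusion_conc(vanco_params(1.5), rate = 1000)
#' @export
steady_state_infusion_conc <- function(params, rate) {
  stopifnot(inherits(params, "pk_params"))
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  rate / params$CL
}
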