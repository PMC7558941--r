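---
title: "Evaluating blood-sampling periods for population PK by stochastic simulation and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating blood-sampling periods for population PK by stochastic simulation and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsse)
```

## The question

Population pharmacokinetic (Pop PK) studies of antibiotics habitually draw
blood after the fourth or fifth dose, when concentrations have reached
steady state — a convention inherited from therapeutic drug monitoring.
Sampling after the *first* dose would be logistically simpler: fewer dosing
records to verify, less opportunity for the patient's physiology to drift,
and less drop-out before the samples are taken. Whether first-dose sampling
costs anything in estimation quality is an empirical question about study
design, and it can be answered without a clinical trial: simulate cohorts
from a known model, re-estimate the parameters from each simulated design,
and compare the estimates with the values used to simulate. This package
implements that stochastic simulation and estimation (SSE) loop end to end
for a two-compartment vancomycin model, with three sampling designs:

* **PK1** — five samples around the first dose,
* **PK2** — five samples around the fourth dose (36–48 h),
* **PK3** — both periods combined.

## The model

Drug disposition follows a linear two-compartment model with constant-rate
intravenous infusion, parameterised by total clearance $CL$, central and
peripheral volumes $V_1$, $V_2$, and intercompartmental clearance $Q$ (mg,
L, h units throughout). With micro-rate constants $k_{10} = CL/V_1$,
$k_{12} = Q/V_1$, $k_{21} = Q/V_2$, the hybrid disposition constants are
the roots of the usual quadratic,

$$\alpha, \beta = \tfrac12\left(k_{10}+k_{12}+k_{21} \pm
\sqrt{(k_{10}+k_{12}+k_{21})^2 - 4k_{10}k_{21}}\right),$$

with coefficients $A = (\alpha - k_{21})/(V_1(\alpha-\beta))$ and
$B = (k_{21}-\beta)/(V_1(\alpha-\beta))$. During an infusion at rate
$R_\mathrm{inf}$,

$$C(t) = R_\mathrm{inf}\left[\frac{A}{\alpha}(1-e^{-\alpha t}) +
\frac{B}{\beta}(1-e^{-\beta t})\right],$$

and after the end of an infusion of duration $t_\mathrm{inf}$ each
exponential term decays from its end-of-infusion value with the elapsed
time $t - t_\mathrm{inf}$ as the exponential argument. That convention is
forced by continuity at $t_\mathrm{inf}$ and is verified in the test suite
against adaptive ODE integration (relative tolerance $10^{-6}$). Multiple
doses superpose because the model is linear. `steady_state_infusion_conc()`
exposes the identity $R_\mathrm{inf}(A/\alpha + B/\beta) =
R_\mathrm{inf}/CL$ as an analytic cross-check. A one-compartment branch
($Q = 0$) exists for testing only.

Between-subject variability (BSV) is exponential,
$\theta_i = \theta\,e^{\eta_i}$ with $\eta_i \sim N(0, \omega^2)$
independently per parameter (diagonal $\Omega$), and residual variability
(RV) is proportional, $y_{ij} = \hat y_{ij}(1 + \sigma\,\varepsilon_{ij})$,
$\varepsilon_{ij}\sim N(0,1)$.

## Study conditions

The simulated regimen is 1000 mg infused every 12 h, four doses, with
infusion durations of 1, 2 or 4 h. Typical values come from a published
vancomycin model for adults: $V_1 = 24.2$ L, $V_2 = 32.3$ L,
$Q = 11.2$ L/h, with $CL \in \{1.5, 4.5\}$ L/h spanning renal function;
$\omega = 0.30$ on all four parameters (30% CV) and $\sigma = 0.10$. Sample
offsets from dose start are fixed per infusion duration
(`sampling_offsets()`): 0, 1, 2, 4, 12 h for 1-h infusions; 0, 2, 3, 5,
12 h for 2-h; 0, 4, 5, 9, 12 h for 4-h. Cohort sizes are 25, 50, 100 and
200, giving the 3 × 2 × 3 × 4 = 72-cell grid of `scenario_grid()`.

Two schedule details deserve note. The pre-dose sample of the *first* dose
has a model prediction of exactly zero, which makes the proportional error
model degenerate there; `simulate_dataset()` emits it with `MDV = 1`
(excluded from fitting) so the schedule stays faithful without an undefined
likelihood contribution. The pre-dose sample of the *fourth* dose is the
36-h trough, which is informative and kept. Negative simulated
concentrations (the Gaussian error is unbounded) are truncated at zero;
with 10% proportional error this is astronomically rare.

Randomness is organised as deterministic substreams: a base seed plus the
scenario and replicate index give the replicate seed, and each subject
draws from a seed derived from the replicate seed and the subject index.
Consequently any replicate is reproducible in isolation and the first 25
subjects of a 200-subject cohort equal the 25-subject cohort under the
same seed.

## Estimation

`fit_ppk()` maximises an approximate marginal likelihood over
$\log\theta$ (4), $\log\omega^2$ (4) and $\log\sigma$ (1); the log scale
enforces positivity. For each subject the *conditional objective*

$$g_i(\eta) = \sum_j\left[\log(2\pi\sigma^2\hat y_{ij}^2) +
\frac{(y_{ij}-\hat y_{ij})^2}{\sigma^2\hat y_{ij}^2}\right] +
\eta^\top\Omega^{-1}\eta + \log|\Omega| + k\log 2\pi$$

is minimised in $\eta$ (the conditional modes, i.e. empirical Bayes
estimates); note the residual variance depends on $\eta$ through
$\hat y_{ij}$, the "interaction" in FOCE-I parlance. The marginal
contribution is then

$$-2\,l_i \approx g_i(\hat\eta_i) + \log\left|\tfrac12 H_i\right| -
k\log 2\pi,$$

where $H_i$ is the Hessian of $g_i$ at the mode. The two supported methods
differ only in $H_i$:

* `"laplace"` (default) — the exact Hessian, by forward finite differences
  of the analytic $\eta$-gradient;
* `"focei"` — the first-order approximation built from model sensitivities
  $\partial f/\partial\eta$ only, with Fisher weights
  $1/v_{ij} + 2/\hat y_{ij}^2$ that include the interaction term.

Model sensitivities are exact: the compiled kernel propagates forward-mode
dual numbers through the closed-form solution, so one pass yields the
prediction and all four $\eta$-derivatives at machine precision (the
pure-R path uses complex-step differentiation; the two implementations are
cross-checked to equality in the tests).

**Why the exact Hessian is the default.** The PK1/PK2 designs give each
subject four or five usable observations against four random effects. In
that regime the conditional posterior is strongly non-Gaussian and the
curvature carried by the model's second derivatives is material: on
one-random-effect instances both methods agree with adaptive Gauss–Hermite
quadrature to well under 0.5 on the $-2\log L$ scale (a test-suite
invariant), but on the full four-effect sparse designs the first-order
Hessian distorts the profile of the objective in $CL$ enough to shift its
minimiser by double-digit percentages, which an importance-sampling check
of the exact marginal likelihood rejects. The exact-Hessian objective
tracks those oracles closely, so it is what the SSE engine uses by
default. `"focei"` remains available and behaves equivalently on
data-rich designs such as PK3.

### Numerical choices

* **Inner problem.** Damped Newton with the Fisher-scoring matrix far from
  the optimum (always positive definite), switching to undamped
  true-Hessian Newton steps once the gradient is small. The switch is not
  cosmetic: scoring steps can cycle where the true curvature differs from
  its expectation, and the final modes must be *path-independent* because
  warm starts across outer iterations would otherwise leave
  hysteresis-level noise in the objective that derivative-based outer
  optimisation amplifies. The iteration targets a gradient norm of
  `inner_tol` ($10^{-8}$); the convergence verdict tolerates subjects
  parked in flat valleys three orders of magnitude above it.
* **Outer problem.** PORT (`nlminb`) with internal differencing; relative
  tolerance $10^{-7}$. On nearly flat ridges (weakly identified variance
  components) PORT may report "false convergence"; the fit restarts from
  the current point and accepts a stationary objective (improvement below
  0.05) as converged.
* **Bounds.** Log-scale box bounds keep volumes and clearances below
  $10^4$ and $\sigma$ below 10. BSV variances are capped at
  $\omega^2 \le 1$ (≈130% CV): beyond that the lognormal BSV model is
  implausible for these parameters, and the approximate objective
  develops a degenerate $\theta \to 0$, $\omega^2 \to \infty$ ridge that
  the exact marginal likelihood (importance-sampling oracle) rejects.
  A solution on an upper bound, or with a collapsed fixed effect, is
  flagged non-converged.
* **Initial values.** The SSE engine initialises at the simulation truth —
  the standard SSE convention. Non-convergent replicates are retried once
  from initials jittered uniformly by ±30%; replicates that still fail are
  excluded from the metrics and reported in `n_converged`.

## Metrics

For each parameter, accuracy and precision over replicates are

$$\mathrm{rBias} = 100\%\cdot\frac1N\sum_i\frac{PE_i - PS}{PS},\qquad
\mathrm{rRMSE} = 100\%\cdot\sqrt{\frac1N\sum_i\left(\frac{PE_i -
PS}{PS}\right)^2},$$

with $PE$ the estimate and $PS$ the simulation truth. Fixed effects are
summarised on the natural scale, BSV on the $\omega^2$ (variance) scale
and RV on the $\sigma$ (SD) scale. $N$ counts converged replicates only.
`evaluate_criteria()` applies the conventional thresholds
$|\mathrm{rBias}| \le 15\%$ and $\mathrm{rRMSE} \le 35\%$. By construction
$\mathrm{rRMSE} \ge |\mathrm{rBias}|$, a property test in the suite.

## Problem sizes used for verification

The full design — 72 scenarios × 200 replicates — is a cluster-scale
computation. The package's own verification uses desk-scale slices chosen
to exercise every part of the grid: the favourable scenario (PK3, 1-h
infusion, $CL = 4.5$, $n = 100$) at 25 replicates, and the 12-cell
sub-grid {PK1, PK2, PK3} × {1.5, 4.5} L/h × 1-h infusion × {25, 200}
subjects at 25 replicates per cell. `scripts/acceptance.R` recomputes all
reported quantities from scratch at these sizes; `run_sse()` defaults to
200 replicates for full-scale use.

## What the generator does and does not emulate

The synthetic cohorts reproduce the stated trial exactly: fixed nominal
sampling times, complete dosing histories, no covariates, diagonal
$\Omega$, and Gaussian proportional error. Real TDM-style data add
covariate-driven parameter heterogeneity, deviations between nominal and
actual sampling/dosing times, assay quantification limits, correlated
random effects and drop-out — none of which are modelled. Passing the SSE
criteria here therefore demonstrates estimator and design behaviour under
the idealised conditions, not robustness to those real-world features.

## Known limitations

* With 25 subjects × 4 usable samples (PK1 at the lower clearance, where
  the terminal half-life far exceeds the sampling window), the data
  genuinely carry little information about $CL$: spot checks with the
  exact-likelihood oracle show individual replicates whose maximum sits
  tens of percent from the truth. Summaries in such cells reflect that
  information limit — a dogged optimiser faithfully reports it, whereas
  truth-initialised runs terminated early by iteration limits can look
  misleadingly precise. Expect some small-sample cells to breach the
  precision criterion for BSV, and structural rRMSE in the hardest cell to
  exceed what richer designs achieve.
* The estimator family conditions on posterior modes; none of the methods
  is exact integration. The quadrature agreement tested on
  one-random-effect instances bounds the approximation there, not in four
  dimensions.
* Standard errors, covariance steps, and covariate search are out of
  scope; the package evaluates designs, it does not build models.
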