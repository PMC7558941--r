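# popsse

Stochastic simulation and estimation (SSE) for evaluating blood-sampling
designs in population pharmacokinetics.

## The problem

Population PK studies of antibiotics conventionally sample blood around
the fourth or fifth dose, at steady state. Sampling around the **first**
dose would make studies cheaper and more robust — but does it cost
estimation quality? `popsse` answers this by simulation: virtual cohorts
are generated from a known two-compartment vancomycin model under three
designs — samples after the first dose (**PK1**), after the fourth dose
(**PK2**), or both (**PK3**) — then re-fitted by nonlinear mixed-effects
estimation, and the recovered parameters are compared with the simulation
truth.

The package is for pharmacometricians and biostatisticians who design PK
sampling schedules or study estimator behaviour on sparse designs.

## The model and metrics

Disposition is a linear two-compartment model with constant-rate IV
infusion. With micro-rate constants k10 = CL/V1, k12 = Q/V1, k21 = Q/V2
and hybrid constants α, β = ½[(k10+k12+k21) ± √((k10+k12+k21)² −
4·k10·k21)], the during-infusion concentration is

    C(t) = R_inf · [ A/α (1 − e^(−αt)) + B/β (1 − e^(−βt)) ],

with A = (α − k21)/(V1(α − β)), B = (k21 − β)/(V1(α − β)); after the end
of the infusion each term decays from its end-of-infusion value. Multiple
doses superpose (linearity). Between-subject variability is exponential,
θᵢ = θ·exp(ηᵢ), ηᵢ ~ N(0, ω²), and residual error is proportional,
yᵢⱼ = ŷᵢⱼ(1 + σ·εᵢⱼ).

Estimation maximises an approximate marginal likelihood built on
per-subject conditional modes: `-2lᵢ ≈ g(η̂ᵢ) + log|Hᵢ/2| − k·log 2π`,
with the exact eta-Hessian (`method = "laplace"`, default) or its
first-order approximation (`method = "focei"`); both include the
residual-variance/eta interaction. Estimator performance per scenario is
summarised by

    rBias  = 100% · mean((PE − PS)/PS)
    rRMSE  = 100% · sqrt(mean(((PE − PS)/PS)²))

with conventional acceptance bounds |rBias| ≤ 15% and rRMSE ≤ 35%.

## A worked example

```r
library(popsse)

sc <- scenario_spec("PK3", CL = 4.5, infusion_duration = 1, n_subjects = 25)
d  <- simulate_dataset(sc, variance_spec(), seed = 7)   # 30% BSV, 10% RV
f  <- fit_ppk(d, init = list(theta = vanco_params(4.5),
                             omega2 = rep(0.09, 4), sigma = 0.1))
f
#> <ppk_fit> laplace fit of 25 subjects (225 observations)
#>   converged: TRUE   objective: 1045.7645
#>   theta:    CL=4.36  V1=24  V2=37.7  Q=13.4
#>   omega^2:  CL=0.122  V1=0.0997  V2=0.0476  Q=0.176
#>   sigma:    0.09506
```

The fixed effects land within ~20% of the simulating values (CL = 4.5,
V1 = 24.2, V2 = 32.3, Q = 11.2) from a single 25-subject cohort; `tidy(f)`
and `glance(f)` give the estimates and fit summary as tibbles. Replicating
simulate-then-fit and summarising:

```r
s <- run_sse(sc, n_replicates = 5, base_seed = 1)
s[, c("term", "scale", "truth", "rbias", "rrmse", "n_converged")]
#>   term      scale    truth   rbias rrmse n_converged
#> 1 CL        natural   4.5    1.63   7.61           5
#> 2 V1        natural  24.2    2.07   8.38           5
#> 3 V2        natural  32.3    8.84   9.41           5
#> 4 Q         natural  11.2   -0.336  5.08           5
#> 5 omega2_CL variance  0.09 -20.4   30.9            5
#> ...
#> 9 sigma     sd        0.1   -1.84   6.57           5
```

Structural parameters are recovered essentially unbiased; the
between-subject variances shrink downward (negative rBias) — the expected
shrinkage of variance components estimated from five samples per subject —
while the residual SD is nearly unbiased. `evaluate_criteria(s)` applies
the 15%/35% bounds, `autoplot(s, metric = "rrmse")` draws the comparison
panels, and `scenario_grid()` enumerates all 72 study cells. A YAML-driven
pipeline (`run_config()`, `sse_simulate()`, `sse_run()`) and a CLI
(`inst/cli/popsse.R` with `simulate`, `fit`, `sse`, `report` subcommands)
wrap the same functions for batch use; datasets are exchanged as
NONMEM-dialect CSV (`ID,TIME,AMT,RATE,EVID,MDV,DV`).

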