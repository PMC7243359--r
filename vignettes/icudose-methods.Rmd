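---
title: "Methods: PK models, simulation, dose finding and MAP individualization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PK models, simulation, dose finding and MAP individualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icudose)
```

## The problem

Critically ill patients clear and distribute antibiotics very differently
from the general population, and their renal function can change within
hours. The package computes individualized dosing regimens from routinely
collected covariates (weight, serum creatinine, age, sex), optionally
refined by measured plasma concentrations, and expresses everything as
absolute, simulation-verified dose advice.

## Population PK models and covariate equations

The registry (`inst/extdata/models.yaml`) ships four published ICU
population models as one- or two-compartment linear structures. Clearance
is individualized by a named covariate form:

| drug | structure | clearance model | central volume |
|---|---|---|---|
| meropenem | 1-cmt | $CL = 11.1 \cdot (\mathrm{mSCR}/0.7)^{-1}$, $\mathrm{mSCR}=\max(\mathrm{SCR}, 0.4)$ mg/dL | 33.6 L |
| ciprofloxacin | 2-cmt | $CL = 18 \cdot (\mathrm{CLcr}/91.7)^{\theta_2}$ | 38 L (Q 60 L/h, V2 73 L) |
| ceftriaxone | 2-cmt | $CL = 0.56 + 0.32 \cdot \mathrm{CLcr}/4.26$ | 10.3 L (Q 5.28 L/h, V2 7.35 L) |
| vancomycin | 1-cmt | $CL = 4.58 \cdot \mathrm{CLcr}/100$ | 1.53 L/kg × body weight |

CLcr is the Cockcroft-Gault creatinine clearance
$(140-\mathrm{age})\cdot\mathrm{weight}/(72\cdot\mathrm{SCR})$, ×0.85 for
women, floored at zero; a measured CLcr in the record takes precedence over
the derived value. Design choices that were genuinely open:

* The meropenem clearance is interpreted as inversely proportional to the
  clamped creatinine (exponent −1 around the 0.7 mg/dL reference); the
  clamp at 0.4 mg/dL prevents runaway clearance at very low creatinine.
* The ciprofloxacin covariate exponent $\theta_2$ is not available from the
  source summary; the registry defaults to 1 (linear) and the value is
  config-overridable. Evaluating at the reference CLcr of 91.7 mL/min is
  exponent-independent, which is what the reference checks use.
* The ceftriaxone clearance equation is implemented as an intercept-plus-
  slope function of CLcr ($\theta_{CL} = 0.56$, $\theta_{CLcr} = 0.32$,
  scaling divisor 4.26); the peripheral volume is taken as 7.35 L (the
  catalogue annotates the unit). Users should verify both against the
  primary publication before clinical-style use.
* Inter-individual variability (IIV) omegas and residual-error sigmas are
  **documented placeholders** (ω 0.25–0.30; additive 1 mg/L and/or
  proportional 15–20%), chosen as typical magnitudes for these drug
  classes. They drive only the synthetic-data generator and the MAP
  prior/likelihood; all deterministic dose calculations are independent of
  them, and a user catalogue can override them.
* No cefotaxime model ships (its parameters are not publicly tabulated);
  `register_model()` accepts a user-supplied specification.

## Simulation engine

Amounts $A_1, A_2$ (mg) follow the linear system
$\dot A_1 = u(t) - (CL/V_1)A_1 - (Q/V_1)A_1 + (Q/V_2)A_2$,
$\dot A_2 = (Q/V_1)A_1 - (Q/V_2)A_2$, with concentration $C = A_1/V_1$.
The solver is the classical fourth-order Runge-Kutta method on a fixed
1-minute grid. Numerical choices:

* **Forcing alignment.** Infusion rates are piecewise constant on the
  grid: event starts are snapped to the nearest minute, durations to whole
  minutes (minimum 1; a bolus is modeled as a 1-minute infusion, matching
  how IV antibiotics are actually given). The rate active at a step's
  start is held through the step, so RK4 never samples a forcing
  discontinuity mid-step and the update reduces to a precomputed affine
  map — exactly the RK4 result for constant input, computed efficiently.
* **Accuracy.** Against the exact closed-form one-compartment solution the
  1-minute RK4 grid agrees to ~1e-13 mg/L on a typical vancomycin
  regimen; halving the step shrinks the error ~16-fold on a
  fast-elimination test problem (fourth-order convergence). The test suite
  also cross-checks the two-compartment path against an independent stiff
  solver (`deSolve::lsoda`).
* **Steady state** is taken as seven terminal half-lives
  ($t_{1/2} = \ln 2 \cdot V_1/CL$ for one compartment; $\ln 2$ over the
  slow disposition exponent for two). For exposure evaluation the settling
  time is rounded **up** to a whole number of dosing intervals and the
  evaluation window (one interval or 24 h, dosed throughout) is appended
  after it, so the window itself sits at ≥ 99.2% of steady state — which
  is why simulation-vs-analytic closure tests hold at the 1–2% level. A
  hard cap of 14 days bounds the horizon for extremely low clearances.
* AUC uses the trapezoidal rule on the grid; %T>MIC is the fraction of
  grid points above the MIC; concentrations are non-negative for
  non-negative inputs by construction.

## Dose calculation

PK linearity is the premise: exposure is proportional to dose, and total
daily exposure is independent of how the daily dose is split.

* **Trough-targeted (time-above-MIC) drugs**: a test dose is simulated to
  steady state at the requested interval and scaled by
  `target trough / simulated trough`. The target trough defaults to
  1 × MIC (configurable multiplier), which guarantees 100 %T>MIC at steady
  state. The result is test-dose independent (asserted by a test).
* **AUC-targeted drugs**: the analytic relation
  $MD_{daily} = AUC^{24}_{target} \times CL$ needs no simulation; splitting
  across the daily frequency is the advisor's job.
* **Loading dose**: by superposition, the concentration at the end of the
  loading infusion decomposes into the decay of what is already in the
  body (`Ct_res`, simulated from the dose history) plus the contribution
  of the LD itself. A test LD simulated from a drug-free state is scaled
  to cover $C_{max}^{ss} - Ct_{res}$, and clamped at zero when the
  residual already reaches the target peak. Its defining contract — the
  concentration at the end of the LD infusion equals the steady-state peak
  within 2%, and the first troughs sit near the steady-state trough — is
  tested on randomized scenarios.

## The dosing advisor

Frequencies are iterated from the drug's baseline (q24h ceftriaxone, q12h
vancomycin/ciprofloxacin, q8h meropenem — package defaults) upward through
{1, 2, 3, 4, 6} administrations/day; five per day is excluded as clinically
unused. For each frequency the MD is computed (per target kind), then three
safety predicates are checked — single dose ≤ max dose, daily total ≤ max
daily dose, simulated steady-state peak < minimal toxic concentration — and
the **first feasible (lowest) frequency wins**. MD safety is checked before
the LD is derived; an LD above the single-dose cap is capped with an
explicit warning (both constraints are always enforced; the order is a
documented choice). If an LD > 0 is needed the advice is
loading-plus-maintenance starting now; otherwise maintenance-only with an
*estimated ideal dosing time*: the first minute at which the residual
concentration from past doses has decayed to the regimen's steady-state
trough (root-bracketing on the simulated residual curve). If no intermittent
regimen is safe and continuous advice is enabled, the rate is
$AUC^{24}_{target}\cdot CL/24$ (AUC targets) or $C_{min}^{target}\cdot CL$
(trough targets), again safety-checked; otherwise the status is NO_ADVICE
with a referral to the support team/pharmacist.

Warnings never alter the advice silently: totals above twice or below half
the standard daily dose, covariates older than their freshness limit
(creatinine 24 h by default), and capped loading doses are all reported.
Advice is stated in absolute terms only — never "increase/decrease by X" —
so it cannot be corrupted by an out-of-date view of the current order.

## MAP individualization

With measured levels $y_j$ at times $t_j$, multiplicative correction
factors $f_{CL}, f_{V_1}$ (only the random-effect-bearing parameters) are
estimated by minimizing

$$-\log \pi(f) = \sum_j \left[ \frac{(y_j - \hat y_j(f))^2}{2\sigma_j^2}
  + \tfrac12\log(2\pi\sigma_j^2)\right]
  + \sum_{p} \frac{(\ln f_p)^2}{2\omega_p^2},$$

with $\sigma_j^2$ from the model's residual kind (additive, proportional in
$\hat y_j$, or combined). The optimizer is simulated annealing over
$\ln f$: Gaussian proposals (SD 0.05), geometric cooling
($T_0 = 1$, α = 0.999/iteration), 5,000 proposal iterations (iterations
count proposals, not acceptances — a documented choice), best-seen state
returned, search space bounded to factors in [0.1, 10]. All settings are
config-exposed; the seed is a required argument and identical seeds give
bit-identical results. For one-compartment models the objective evaluates
the exact closed-form solution rather than re-integrating the ODE at every
iteration — numerically identical for these linear models and roughly two
orders of magnitude faster; two-compartment models use the RK4 grid. A
dense grid search over a one-factor posterior is used as an independent
oracle in the tests.

## Synthetic cohorts

`generate_patient()` emulates an ICU extraction: age uniform on 18–90 y,
weight normal (80 ± 20 kg), serum creatinine lognormal (median 1 mg/dL,
log-SD 0.5), all clipped to configured ranges; creatinine follows a
multiplicative lognormal random walk across covariate timestamps (default
log-SD 0.1/day) to emulate evolving renal function. Observed levels add
lognormal IIV on CL/V1 and the model's residual noise, truncated at zero.
What this deliberately does **not** emulate: covariate measurement error,
within-day parameter changes (parameters are held at the covariate set in
force at advice time), dosing-record errors, assay quantification limits,
and nonlinear (saturable) elimination — ceftriaxone's known concentration-
dependent protein binding is outside the linear-model scope. Passing tests
therefore demonstrate internal correctness of the algorithms under the
models' own assumptions, not clinical performance on real patients.

The regimen-evaluation harness scores each patient's simulated steady-state
24-h window for percent time in the 10–30 mg/L range and AUC0-24 against
400–600 mg·h/L, mirroring how a retrospective advice-vs-TDM comparison
would be scored; the comparator strategy is caller-supplied.

## Problem sizes used by the test suite

Chosen to probe each property at meaningful scale: 200–1,000 synthetic
patients for range/safety sweeps, 50 seeded replicates for MAP parameter
recovery (meropenem 1 g q8h, four samples at end-of-infusion and
mid-interval over two dosing cycles — a design that informs both CL and
V1), 10,000 draws for distributional checks, 20 randomized scenarios for
the loading-dose contract, and 48-h grids at 1-minute resolution for
solver accuracy.

## Known limitations

* Trough-only sampling leaves the volume factor weakly identified: with
  sparse troughs the MAP prior dominates $f_{V_1}$ and estimates shrink
  toward 1. This is a statistical property of the design, not an optimizer
  artifact; sampling near the end of infusion restores identifiability,
  which is why the recovery experiment uses peak + mid-interval samples.
* Linear PK throughout; no saturable clearance or protein-binding
  corrections.
* Individual parameters are constant within a simulation (the covariate
  set in force at advice time); time-varying covariates influence repeated
  advice, not a single simulated curve.
* The shipped IIV/residual magnitudes are placeholders pending the source
  models' published estimates; conclusions that depend on them (synthetic
  noise levels, MAP shrinkage strength) should be re-examined against a
  locally calibrated catalogue.
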