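# icudose

Model-informed precision dosing (MIPD) of antibiotics for critically ill
patients, in R.

Antibiotic pharmacokinetics (PK) in the ICU are highly variable — up to
several-hundred-fold differences in plasma concentration have been observed
between critically ill patients on identical regimens — and standard dosing
frequently misses the pharmacodynamic target. `icudose` implements the
computational core of a bedside dosing decision-support workflow for
pharmacometricians and clinical-pharmacology researchers:

* a **registry of published population PK models** (meropenem,
  ciprofloxacin, ceftriaxone, vancomycin) with their covariate equations on
  clearance (Cockcroft-Gault creatinine clearance, serum creatinine with a
  0.4 mg/dL clamp, body-weight-scaled volume), plus user-supplied models;
* a **fixed-step classical Runge-Kutta (RK4) ODE solver** for one- and
  two-compartment linear models with infusion schedules on a 1-minute grid,
  with an exact closed-form one-compartment solution as the built-in
  reference;
* **dose calculators** built on PK linearity: the scaling rule
  `MD_target = (exposure_target / exposure_test) × MD_test`, the analytic
  AUC relation `MD_daily = AUC24_target × CL`, and a superposition-based
  loading dose that reaches the steady-state peak `C_max` immediately,
  accounting for residual drug `Ct_res` from earlier doses;
* a **clinical dosing advisor** that iterates dosing frequencies (up to six
  administrations daily), enforces safety limits (maximum single and daily
  dose, minimal toxic peak concentration), warns on doses outside half-to-
  double the standard daily dose and on stale covariates, and falls back to
  a continuous infusion or an explicit no-advice referral;
* a **Bayesian maximum a posteriori (MAP) estimator** that individualizes
  clearance and central volume from measured plasma levels via seeded
  simulated annealing over multiplicative correction factors with a
  lognormal IIV prior;
* a **synthetic ICU cohort generator** and paired regimen-evaluation
  harness (percent time in the 10–30 mg/L window, AUC0-24 against
  400–600 mg·h/L) for end-to-end testing without patient data.

## Worked example

```r
library(icudose)

cv  <- data.frame(time_h = 0, weight_kg = 70, scr_mg_dl = 1.0,
                  age_years = 40, sex = "male")
pat <- patient_record("icu-001", cv)

params <- compute_individual_parameters(get_model("vancomycin"),
                                        latest_covariates(pat))
#> CL = 4.452778 L/h; V1 = 107.1 L

advise("vancomycin", pat)
#> Dosing advice for vancomycin:
#>   Loading dose: 2822 mg infused over 60 min, starting at t = 0.0 h.
#>   Maintenance dose: 1113 mg every 12 h (infused over 60 min), starting one interval after the loading dose, at t = 0.0 h.
#>   Predicted steady state: AUC0-24 498 mg*h/L, Cmin 16.3 mg/L, Cmax 25.9 mg/L, %T>MIC 100%.
```

Reading the output: the covariate model converts this patient's
Cockcroft-Gault creatinine clearance (97.2 mL/min) into an individual
clearance of 4.45 L/h; the advisor targets a vancomycin AUC0-24 of
500 mg·h/L (the middle of the desirable 400–600 range), giving a daily dose
of `500 × 4.45 ≈ 2226 mg` split as 1113 mg every 12 h, and a loading dose
sized so the concentration at the end of its infusion already equals the
steady-state peak. The predicted steady-state AUC of 498 mg·h/L is read
back from a full re-simulation of the advised regimen (the 0.4% gap to the
analytic target is the finite settling horizon of seven half-lives).

If the patient record contains measured plasma levels, `map_estimate()`
(run automatically by the `advise` CLI verb) first fits correction factors
on CL and V1 and the advice uses the individualized parameters.

A command-line interface covers the same workflow
(`exec/icudose advise|simulate|fit|synth|evaluate`).

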