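# Population PK model catalogue for ICU antibiotic dosing.
#
# Each entry defines the structural model (1 or 2 compartments), typical
# parameter values, the covariate equation on clearance as a named form with
# coefficients, inter-individual variability (IIV, lognormal omega on the
# named parameters) and the residual-error model.
#
# IIV omegas and residual sigmas are documented placeholder values (the
# source publications' estimates are not reproduced here); they drive only
# the synthetic-cohort generator and the MAP prior/likelihood and may be
# overridden by a user-supplied catalogue.
meropenem:
  source: Muro 2011
  source_id: "21366653"
  n_compartments: 1
  typical:
    cl: 11.1        # L/h at reference mSCR 0.7 mg/dL
    v1: 33.6        # L
  covariate_model:
    cl:
      form: power_scr
      theta: 11.1
      ref_scr: 0.7
      exponent: -1.0
      scr_floor: 0.4   # mSCR clamp: SCR below 0.4 mg/dL treated as 0.4
  iiv:
    cl: 0.30
    v1: 0.25
  residual_error:
    kind: additive
    sigma_add: 1.0     # mg/L
  baseline_interval_h: 8
  max_daily_frequency: 6
ciprofloxacin:
  source: Khachman 2011
  source_id: "21653603"
  n_compartments: 2
  typical:
    cl: 18.0        # L/h at reference CLcr 91.7 mL/min
    v1: 38.0        # L
    q: 60.0         # L/h
    v2: 73.0        # L
  covariate_model:
    cl:
      form: power_clcr
      theta: 18.0
      ref_clcr: 91.7
      exponent: 1.0    # exponent not published; linear default, overridable
  iiv:
    cl: 0.30
    v1: 0.25
  residual_error:
    kind: proportional
    sigma_prop: 0.20
  baseline_interval_h: 12
  max_daily_frequency: 6
ceftriaxone:
  source: Garot 2011
  source_id: "21545483"
  n_compartments: 2
  typical:
    cl: 0.56        # L/h intercept
    v1: 10.3        # L
    q: 5.28         # L/h
    v2: 7.35        # L
  covariate_model:
    cl:
      form: intercept_clcr
      theta: 0.56
      theta_clcr: 0.32
      ref_clcr: 4.26   # CLcr scaling divisor (Cockcroft-Gault, mL/min)
  iiv:
    cl: 0.30
    v1: 0.25
  residual_error:
    kind: proportional
    sigma_prop: 0.20
  baseline_interval_h: 24
  max_daily_frequency: 6
vancomycin:
  source: Roberts 2011
  source_id: "21402850"
  n_compartments: 1
  typical:
    cl: 4.58        # L/h at reference CLcr 100 mL/min
    v1: 1.53        # L/kg (scaled by body weight)
  covariate_model:
    cl:
      form: linear_clcr
      theta: 4.58
      ref_clcr: 100.0
    v1:
      form: per_kg
      theta: 1.53
  iiv:
    cl: 0.30
    v1: 0.25
  residual_error:
    kind: combined
    sigma_add: 1.0
    sigma_prop: 0.15
  baseline_interval_h: 12
  max_daily_frequency: 6
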