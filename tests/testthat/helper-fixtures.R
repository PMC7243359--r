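# Shared fixtures: a reference adult ICU patient and convenience builders.

ref_cov <- function(...) {
  covariate_set(weight_kg = 70, scr_mg_dl = 1.0, age_years = 40, sex = "male", ...)
}

ref_patient <- function(clcr_ml_min = 100, doses = NULL, observations = NULL) {
  cv <- data.frame(time_h = 0, weight_kg = 70, scr_mg_dl = 1.0, age_years = 40,
                   sex = "male", clcr_ml_min = clcr_ml_min)
  patient_record("ref", cv, doses = doses, observations = observations)
}

# Regimen of repeated identical infusions starting at t = 0.
regular_events <- function(md_mg, interval_h, n_doses, infusion_min = 60) {
  dose_events(amount_mg = md_mg, time_h = (seq_len(n_doses) - 1) * interval_h,
              infusion_min = infusion_min)
}

# A one-compartment model with clearance-only IIV and additive error, for
# one-factor MAP problems.
one_factor_model <- function(sigma_add = 1, omega_cl = 0.3) {
  pk_model("testdrug", 1, typical = list(cl = 5, v1 = 50),
           iiv = list(cl = omega_cl),
           residual_error = list(kind = "additive", sigma_add = sigma_add),
           baseline_interval_h = 12)
}
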