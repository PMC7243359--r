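# Per-drug clinical configuration: exposure targets, safety limits,
# administration defaults and covariate-freshness limits for the advisor.
# Values are package defaults chosen from common ICU dosing references and
# are meant to be reviewed/overridden locally.
meropenem:
  target:
    kind: T_ABOVE_MIC
    mic_mg_l: 2.0
    cmin_mic_multiplier: 1.0      # target trough = multiplier * MIC
  limits:
    max_dose_mg: 2000
    max_daily_dose_mg: 6000
    minimal_toxic_conc_mg_l: 80
    standard_daily_dose_mg: 3000  # 1 g q8h
  infusion_min: 30
  continuous_enabled: true
  freshness_h:
    scr_mg_dl: 24
    weight_kg: 168
ciprofloxacin:
  target:
    kind: AUC_OVER_MIC
    mic_mg_l: 0.5
    target_auc24_mg_h_l: 40       # ~ AUC/MIC 80 at MIC 0.5 mg/L
    acceptable_auc_range: [30, 60]
  limits:
    max_dose_mg: 800
    max_daily_dose_mg: 1600
    minimal_toxic_conc_mg_l: 15
    standard_daily_dose_mg: 800   # 400 mg q12h
  infusion_min: 60
  continuous_enabled: false
  freshness_h:
    scr_mg_dl: 24
    weight_kg: 168
ceftriaxone:
  target:
    kind: T_ABOVE_MIC
    mic_mg_l: 1.0
    cmin_mic_multiplier: 1.0
  limits:
    max_dose_mg: 2000
    max_daily_dose_mg: 4000
    minimal_toxic_conc_mg_l: 300
    standard_daily_dose_mg: 2000  # 2 g q24h
  infusion_min: 30
  continuous_enabled: false
  freshness_h:
    scr_mg_dl: 24
    weight_kg: 168
vancomycin:
  target:
    kind: AUC_OVER_MIC
    mic_mg_l: 1.0
    target_auc24_mg_h_l: 500      # middle of the desirable 400-600 mg*h/L
    acceptable_auc_range: [400, 600]
    acceptable_conc_range: [10, 30]
  limits:
    max_dose_mg: 3000
    max_daily_dose_mg: 6000
    minimal_toxic_conc_mg_l: 60
    standard_daily_dose_mg: 2000  # 1 g q12h
  infusion_min: 60
  continuous_enabled: true
  freshness_h:
    scr_mg_dl: 24
    weight_kg: 168
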