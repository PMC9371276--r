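# "swiss-gp" synthetic scenario: a desk-scale general-practice EMR with
# patients clustered in GPs, elderly-skewed ages and declining renal
# function, calibrated so that cohort demographics and indicator
# achievement rates land in the range reported for Swiss primary care.
n_gps: 100
patients_per_gp: 60
patients_dispersion: 8
sigma_b:
  rf_testing: 1.2
  albuminuria_testing: 1.1
  raas: 0.5
  statin: 0.5
  nsaid: 0.5
baseline_logit:
  rf_testing: -1.75
  albuminuria_testing: -3.7
  raas: -1.6
  statin: 0.1
  nsaid: -3.2
fixed_effect_log_odds:
  male: 0.2
  diabetes: 0.4
  hypertension: 0.1
  ecvd: 0.2
prevalence:
  diabetes: 0.10
  hypertension: 0.30
  ecvd: 0.10
visits_per_year: 4
egfr_intercept: 100
egfr_age_slope: 0.9
egfr_sd: 15
egfr_annual_decline: 1.2
creatinine_cv: 0.06
study_window: ["2013-01-01", "2019-12-31"]
seed: 1
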