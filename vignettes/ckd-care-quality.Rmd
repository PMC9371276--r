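---
title: "Measuring quality and physician-level variation of CKD care in primary-care EMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring quality and physician-level variation of CKD care in primary-care EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdqi)
```

## The problem

Chronic kidney disease (CKD) is common in general practice and largely
managed by general practitioners (GPs). Guidelines recommend screening
patients with predisposing conditions (diabetes, hypertension, established
cardiovascular disease), staging renal function by estimated glomerular
filtration rate (eGFR) and albuminuria, monitoring established disease, and
adjusting medication — yet how consistently individual GPs do this is hard
to see without measurement. `ckdqi` turns raw longitudinal EMR tables into
two analysis cohorts, evaluates fourteen quality indicators (QIs) over
them, and quantifies how much of the variation in indicator achievement
sits at the level of the individual GP.

The pipeline has six stages, each usable on its own:

1. **Data model** (`read_emr_tables()`): six delimited tables — patients,
   GPs, encounters (ICPC-2 coded), prescriptions (ATC coded), laboratory
   results, vitals — validated and converted to canonical units, with an
   ingestion report counting rejected rows per table and reason.
2. **Renal function** (`ckd_epi_egfr()`, `stage_g()`, `stage_a()`,
   `detect_ckd_all()`): eGFR from serum creatinine, KDIGO staging, and
   laboratory CKD case detection.
3. **Condition rules** (`load_rule_set()`, `label_conditions()`): a
   configurable rule engine dating the first evidence of each predisposing
   condition.
4. **Cohorts** (`build_baseline()`, `build_rf_cohort()`,
   `build_ckd_cohort()`).
5. **Quality indicators** (`evaluate_qi()`, `evaluate_all()`).
6. **Variation statistics** (`fit_random_intercept_logistic()`,
   `analyse_qi_variation()`): odds ratios, intraclass correlation
   coefficients (ICC) and range odds ratios (rOR).

A synthetic EMR generator (`generate_emr()`) with exported ground truth
closes the loop: every stage is testable end to end without access to any
real clinical database.

## Case detection and staging

eGFR is estimated with the 2009 CKD-EPI creatinine equation. The ethnicity
coefficient is omitted deliberately: anonymised primary-care exports carry
no ethnicity field, and in the Swiss setting the affected population share
is small. Where a laboratory reports an eGFR value directly, the reported
value takes precedence and creatinine-based derivation is used only in its
absence.

A patient acquires laboratory evidence of CKD upon **two** abnormal values
of the **same** criterion at least three months apart: eGFR < 60
mL/min/1.73 m², urinary albumin concentration (UAC) ≥ 20 mg/L, or
albumin-to-creatinine ratio (ACR) ≥ 3 mg/mmol. Decisions baked into
`detect_ckd()` and worth knowing:

* *"Three months"* is 90 days (configurable via
  `ckd_detection_config()`). Day arithmetic avoids calendar-month
  ambiguity.
* The two qualifying values need not be consecutive; intervening normal
  values never reset a criterion. Consequently adding data can only keep
  or advance — never remove — a confirmation, a property the test suite
  asserts on randomised series.
* The **evidence date** is the date of the *second* (confirming)
  measurement: two values are required before CKD can be asserted, and all
  follow-up windows anchor there. Under the alternative reading (first
  abnormal value) every monitoring window would shift earlier by the gap
  length.
* The stage at inclusion is the stage current at confirmation: the most
  recent eGFR (for the G stage) and ACR (for the A stage) at or before the
  evidence date. UAC has no A-stage binning, so the A stage is missing for
  patients observed only through UAC.

Stage boundaries follow the KDIGO prognostic grid, inclusive at the lower
edge of each eGFR range (60.0 is G2, 59.99 is G3a) and with ACR 3 and 30
both inside A2.

## Cohorts

The **baseline population** holds everyone with at least one consultation
during the study window (default 2013-01-01 to 2019-12-31) and aged at
least 18 at their first observed event. Two partially overlapping cohorts
are drawn from it:

* the **RF assessment cohort** — patients with a predisposing condition and
  at least 18 months between that condition's first evidence and their last
  recorded contact. Eligibility is tracked per condition, so each
  assessment QI uses its own condition's index date;
* the **CKD care cohort** — patients with confirmed laboratory CKD,
  excluding anyone ever staged G5 (eGFR < 15 anywhere in the record), since
  such patients are typically referred out of primary care and their
  follow-up data are incomplete.

Observation end is operationalised as the last recorded contact of any
event type; the data carry no explicit censoring date. Window constants are
deliberate, documented choices: 18 months = 548 days, 12 months = 365 days,
follow-up in months = days / 30.4375, and event windows are open at the
index date — the measurement that confirms CKD does not double as its own
follow-up monitoring (switchable via `qi_config(count_index_date = TRUE)`).

## The fourteen indicators

Four categories: *assessment* (QIs 1–3: renal-function testing within 18
months of first evidence of diabetes, hypertension, eCVD), *monitoring*
(QIs 4–8: stage-appropriate follow-up testing within 18 months of CKD
confirmation), *medication* (QIs 9–11: RAAS-inhibitor presence, statin
presence at ages 50–80, NSAID absence, within 12 months), and *treatment
targets* (QIs 12–14: latest blood pressure below 140/90 mmHg — 130/80 for
diabetics — and latest BMI in [20, 25]).

Event semantics are fixed in `qi_config()`: renal-function assessment is
any creatinine/eGFR/ACR/UAC measurement; blood chemistry is urea, sodium
or potassium; the mineral-and-bone screen is alkaline phosphatase,
calcium, phosphate or parathyroid hormone; RAAS inhibitors are ATC `C09*`;
statins are `C10AA*`/`C10B*`; NSAIDs are `M01A*` with acetylsalicylic-acid
codes (`B01AC06`, `N02BA01`, `M01BA*`) never counting. A prescription is
"active within 12 months" when it starts inside the window or its
start–end interval overlaps it — the permissive reading, since source
databases do not always carry end dates. Blood-pressure targets require
both components of the latest *complete* reading to be strictly below
threshold; incomplete readings are skipped when choosing the latest. BMI
comes from the recorded value or, failing that, from weight/height².

Each `evaluate_qi()` call returns per-patient denominator and achievement
flags plus the achievement rate (100 × numerator / denominator); the test
suite checks the engine against an independent straight-line recount per
patient.

## Variation statistics

For each indicator, achievement within the denominator is modelled as a
random-intercept logistic regression with patients clustered in GPs:

$$\operatorname{logit} P(y_{ig} = 1) = x_{ig}'\beta + b_g,\qquad
  b_g \sim N(0, \sigma_b^2).$$

Fitting is delegated to `lme4::glmer` (Laplace approximation by default,
adaptive Gauss–Hermite via `nagq`), with listwise deletion of rows with
missing covariates and automatic dropping of covariates left constant in a
denominator. Patients of "other" gender are excluded from model rows (they
are retained in descriptive output). Two models are fitted per indicator:

* the **full model** — patient covariates (gender, age category at index,
  condition flags) plus GP covariates (gender, age category, practice
  urbanity) — supplies the odds-ratio table with Wald 95% intervals
  (`exp(β ± 1.96·SE)`; profile intervals would be more exact but far more
  expensive at this scale, and the Wald convention matches how such tables
  are usually reported);
* the **null model** — GP-level fixed effects omitted, so GP influence
  loads entirely on the random intercept — supplies the variation
  summaries.

Variation is reported on two complementary scales. The **ICC** uses the
latent-response variance partition for logistic models,
$\sigma_b^2 / (\sigma_b^2 + \pi^2/3)$: the share of latent outcome
variance attributable to the GP. The **range odds ratio** is
$e^{q_{95} - q_{05}}$ over the predicted (conditional-mode) intercepts:
the odds multiplier separating a 95th- from a 5th-percentile GP, read on
the same scale as a fixed-effect OR. The central 90% rather than the full
range damps outlier GPs. Percentiles use linear interpolation between
order statistics (R's default type 7) — worth stating because the rOR is
sensitive to the estimator at small cluster counts. Conditional modes are
shrunken toward zero, so the empirical rOR slightly understates the
population value $e^{2 \cdot 1.6449\,\sigma_b} = e^{3.2897\,\sigma_b}$;
with ~100 observations per cluster the attenuation is a few percent, and
the test suite verifies convergence to the analytic limit at 500 clusters
within that tolerance.

## The synthetic generator

`generate_emr()` draws a fully linked EMR under a
`simulation_config()` (the shipped scenario file is
`inst/extdata/swiss_gp.yaml`). What it emulates:

* patients clustered within GPs (negative-binomial list sizes), with one
  **independent GP random intercept per care behaviour** — RF-test
  ordering, albuminuria-test ordering, RAAS/statin/NSAID prescribing —
  rather than a single shared "GP quality" factor, matching the per-QI
  modelling; a correlation parameter would be a config extension;
* a homogeneous Poisson visit process (default 4 visits/patient-year,
  typical of elderly primary-care contact);
* a latent linearly declining eGFR per patient (faster under
  diabetes/hypertension), converted to serum creatinine by inverting the
  CKD-EPI equation, with lognormal measurement noise; ACR/UAC from a
  patient-level lognormal albuminuria propensity;
* episodic behaviours (test ordering, NSAID scripts) drawn **per visit**;
  persistent therapies (RAAS inhibitors, statins) drawn **per patient**
  with repeat scripts at visits — an early lesson from pilot runs was that
  modelling persistent therapy as independent per-visit coin flips drives
  lifetime exposure to 100% and destroys the prescribing indicators;
* blood pressure as a patient-level true value with narrow per-reading
  noise (so chronic hypertension is a patient property, not an artefact of
  reading noise accumulating over many visits), lowered under
  antihypertensive treatment;
* condition onsets emitting ICPC-2 codes, ATC prescriptions and HbA1c
  values that the rule engine can rediscover.

Default intercept SDs (1.2 and 1.1 for the two testing behaviours, 0.5 for
prescribing) map through the latent-scale formulas to ICCs of roughly 0.30
and 0.07 — the span reported for testing versus prescribing indicators in
primary-care studies. Baseline logits were calibrated by pilot simulation
so that cohort composition and achievement rates land in realistic ranges
(assessment ≈ 75–80%, albuminuria monitoring ≈ 20%, NSAID withholding ≈
80%). The calibration is deliberately loose: the diabetic blood-pressure
target (QI 13) runs low against published figures, because the generator's
Gaussian blood-pressure model is not tuned per subgroup. What the
generator does **not** model: referral, death and drop-out (censoring is
purely visit-process-driven), seasonality, laboratory batch effects,
within-GP practice structure (two-level clustering only), and coding error
beyond what the rule approximations absorb. Passing tests therefore
demonstrate correctness of the machinery under the stated generative
assumptions, not calibration to any real population.

Default problem sizes are chosen for desk-scale reproducibility: 100 GPs
with ~60 patients each for pipeline runs, and 200 clusters × 100
observations (50 replicates) or 500 clusters × 100 for the
parameter-recovery and analytic-limit studies of the model machinery.

## Numerical and degenerate-input behaviour

* `glmer` is run with conservative settings; singular fits (σ̂_b = 0) are
  legitimate and reported as ICC 0, rOR 1.
* Fewer than two clusters, non-binary outcomes, and empty denominators
  are hard errors; the pipeline skips model fitting for denominators
  below `min_denominator` (default 50) rather than reporting unstable
  estimates.
* Ages are year-resolution (birth year only), dates day-resolution.
* Ties in CKD criteria firing on the same date resolve in the order eGFR,
  UAC, ACR.
* The rOR is location-invariant in the intercepts and ≥ 1 by
  construction.

## Known limitations

* The default condition rules are documented approximations; exact
  replication of any particular study requires its validated code lists,
  dropped in via `load_rule_set()`.
* Deposited real-world cohort datasets are not redistributable here; the
  replication path (`read_cohort_export()`) is exercised against the
  package's own cohort exports.
* Practice-level clustering (GPs nested in practices) is out of scope; the
  models use GP-level intercepts only.
* No multiple-testing adjustment is applied across indicators, and no
  Bayesian or random-slope variants are provided.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(synth = simulation_config(n_gps = 40, patients_per_gp = 50),
                  seed = 7, out_dir = "ckdqi_out")
res <- run_pipeline(cfg)
res$summary
res$variation$qi1
```

The output bundle contains the cohort characteristics table, cohort
membership exports, the per-indicator summary (rate, rOR, ICC), per-model
forest tables and JSON summaries, per-patient flags, and a manifest
sufficient to reproduce the run byte-for-byte.
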