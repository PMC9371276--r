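Package: ckdqi
Title: Quality-of-Care Indicators and Physician-Level Variation for
    Chronic Kidney Disease in Primary Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for assessing quality of chronic kidney disease
    (CKD) care from longitudinal general-practice electronic medical
    records. Detects laboratory-defined CKD from serum creatinine
    (via the CKD-EPI equation), estimated glomerular filtration rate and
    albuminuria measurements with KDIGO G/A staging; labels predisposing
    conditions (diabetes, hypertension, established cardiovascular
    disease) with a configurable rule engine over ICPC-2 and ATC codes;
    builds a renal-function assessment cohort and a CKD care cohort;
    evaluates fourteen quality indicators covering assessment,
    monitoring, medication and treatment targets; and quantifies
    physician-level variation in indicator achievement with
    random-intercept logistic regression, reporting odds ratios,
    latent-scale intraclass correlation coefficients and range odds
    ratios over the central 90 percent of predicted intercepts. A
    synthetic EMR generator with exported ground truth supports
    end-to-end validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
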