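#' Estimate GFR with the CKD-EPI (2009) creatinine equation
#'
#' Computes the estimated glomerular filtration rate from serum creatinine,
#' age and sex. The ethnicity coefficient is omitted: the data model carries
#' no ethnicity, so eGFR is
#' \deqn{141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
#'       \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot
#'       1.018^{[female]}}
#' with creatinine in mg/dL (converted internally from \eqn{\mu}mol/L by
#' dividing by 88.42), \eqn{\kappa = 0.7} (female) or \eqn{0.9} (male) and
#' \eqn{\alpha = -0.329} (female) or \eqn{-0.411} (male).
#'
#' @param scr Serum creatinine in \eqn{\mu}mol/L (vectorised).
#' @param age Age in years (>= 18).
#' @param sex `"female"`, `"male"`, or `"other"`; creatinine-derived eGFR is
#'   undefined for `"other"` and returns `NA` (a laboratory-reported eGFR is
#'   still usable downstream).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckd_epi_egfr <- function(scr, age, sex) {
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (any(!is.na(scr) & scr <= 0)) abort_ckdqi("scr must be positive")
  if (any(!is.na(age) & age < 18)) abort_ckdqi("adult equation requires age >= 18")
  if (!all(sex %in% c("female", "male", "other") | is.na(sex))) {
    abort_ckdqi("sex must be 'female', 'male' or 'other'")
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  scr_mgdl <- scr / 88.42
  ratio <- scr_mgdl / kappa
  out <- 141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1)
  out[is.na(sex) | sex == "other"] <- NA_real_
  out
}

#' KDIGO G (eGFR) staging
#'
#' Bins eGFR into the prognostic categories G1 (>= 90), G2 (60-89),
#' G3a (45-59), G3b (30-44), G4 (15-29) and G5 (< 15 mL/min/1.73 m^2);
#' boundaries are inclusive at the lower edge of each range.
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (vectorised; `NA` propagates).
#' @return Factor with levels G1..G5.
#' @export
stage_g <- function(egfr) {
  egfr <- as.numeric(egfr)
  if (any(!is.na(egfr) & egfr < 0)) abort_ckdqi("egfr must be non-negative")
  cut(egfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf), right = FALSE,
      labels = c("G5", "G4", "G3b", "G3a", "G2", "G1")) |>
    factor(levels = c("G1", "G2", "G3a", "G3b", "G4", "G5"))
}

#' KDIGO A (albuminuria) staging
#'
#' Bins the albumin-to-creatinine ratio into A1 (< 3), A2 (3-30) and
#' A3 (> 30 mg/mmol); 3 and 30 both fall in A2.
#'
#' @param acr ACR in mg/mmol (vectorised; `NA` propagates).
#' @return Factor with levels A1, A2, A3.
#' @export
stage_a <- function(acr) {
  acr <- as.numeric(acr)
  if (any(!is.na(acr) & acr < 0)) abort_ckdqi("acr must be non-negative")
  # closures differ at the two edges: [3, 30] is A2 (3 -> A2, 30 -> A2)
  out <- ifelse(acr < 3, "A1", ifelse(acr <= 30, "A2", "A3"))
  factor(out, levels = c("A1", "A2", "A3"))
}

#' Build per-date renal-function measurements from the lab table
#'
#' Collapses the laboratory rows of one or more patients into one row per
#' patient-date carrying eGFR (laboratory-reported when available, otherwise
#' derived from serum creatinine with [ckd_epi_egfr()] — derivation happens
#' only where no reported eGFR exists for that date), ACR and UAC.
#'
#' @param dataset An `emr_dataset`.
#' @return Tibble with columns `patient_id`, `date`, `egfr`, `egfr_source`
#'   (`"reported_egfr"` or `"derived_from_creatinine"`), `acr`, `uac`,
#'   sorted by patient and date.
#' @export
rf_measurements <- function(dataset) {
  labs <- dataset$labs
  rf <- labs[labs$analyte %in% c("serum_creatinine", "egfr", "acr", "uac"), ]
  if (!nrow(rf)) {
    return(tibble::tibble(patient_id = character(), date = as.Date(character()),
                          egfr = numeric(), egfr_source = character(),
                          acr = numeric(), uac = numeric()))
  }
  wide <- rf |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("patient_id", "date", "analyte")) |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  for (col in c("serum_creatinine", "egfr", "acr", "uac")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- dplyr::left_join(
    wide, dataset$patients[c("patient_id", "gender", "birth_year")],
    by = "patient_id")
  need_derive <- is.na(wide$egfr) & !is.na(wide$serum_creatinine)
  age <- age_at(wide$birth_year, wide$date)
  derivable <- need_derive & wide$gender %in% c("female", "male") &
    !is.na(age) & age >= 18
  src <- ifelse(is.na(wide$egfr), NA_character_, "reported_egfr")
  if (any(derivable)) {
    wide$egfr[derivable] <- ckd_epi_egfr(wide$serum_creatinine[derivable],
                                         age[derivable],
                                         wide$gender[derivable])
    src[derivable] <- "derived_from_creatinine"
  }
  out <- tibble::tibble(
    patient_id = wide$patient_id, date = wide$date,
    egfr = wide$egfr, egfr_source = src, acr = wide$acr, uac = wide$uac
  )
  out <- out[!(is.na(out$egfr) & is.na(out$acr) & is.na(out$uac)), ]
  dplyr::arrange(out, .data$patient_id, .data$date)
}

#' Laboratory CKD case detection thresholds
#'
#' @param egfr_below eGFR threshold (mL/min/1.73 m^2); values strictly below
#'   qualify. Default 60.
#' @param uac_at_least UAC threshold (mg/L); values at or above qualify.
#'   Default 20.
#' @param acr_at_least ACR threshold (mg/mmol); values at or above qualify.
#'   Default 3.
#' @param min_gap_days Minimum separation of the two qualifying measurements,
#'   in days. "At least 3 months apart" is operationalised as >= 90 days.
#' @return List of class `ckd_detection_config`.
#' @export
ckd_detection_config <- function(egfr_below = 60, uac_at_least = 20,
                                 acr_at_least = 3, min_gap_days = 90L) {
  stopifnot(egfr_below > 0, uac_at_least > 0, acr_at_least > 0,
            min_gap_days >= 0)
  structure(list(egfr_below = egfr_below, uac_at_least = uac_at_least,
                 acr_at_least = acr_at_least, min_gap_days = min_gap_days),
            class = "ckd_detection_config")
}

# Earliest confirming (second-of-pair) date for one criterion: among
# qualifying dates, the first one at least `gap` days after the earliest
# qualifying date. Equivalent to minimising over all qualifying pairs.
confirm_date <- function(dates, qualifies, gap) {
  d <- sort(unique(dates[qualifies]))
  if (length(d) < 2L) return(as.Date(NA))
  hit <- d[d - d[1] >= gap]
  if (length(hit)) hit[1] else as.Date(NA)
}

#' Detect laboratory-defined CKD in one patient's measurement series
#'
#' A patient is labelled CKD-affected upon two eGFR values below 60
#' mL/min/1.73 m^2, and/or two UAC values >= 20 mg/L, and/or two ACR values
#' >= 3 mg/mmol, the pair at least `min_gap_days` apart (criteria evaluated
#' independently; the two values of a pair must belong to the same
#' criterion). The evidence date is the earliest confirming second-of-pair
#' date across criteria; intervening normal values never reset a criterion.
#'
#' @param series Tibble as returned by [rf_measurements()] for a single
#'   patient (columns `date`, `egfr`, `acr`, `uac`), sorted by date.
#' @param config A [ckd_detection_config()].
#' @return One-row tibble: `ckd_confirmed`, `evidence_date`, `criterion`
#'   (`"egfr"`, `"uac"` or `"acr"`), `g_stage_at_inclusion`,
#'   `a_stage_at_inclusion`, `ever_g5`.
#' @export
detect_ckd <- function(series, config = ckd_detection_config()) {
  stopifnot(inherits(config, "ckd_detection_config"))
  empty <- tibble::tibble(
    ckd_confirmed = FALSE, evidence_date = as.Date(NA),
    criterion = NA_character_,
    g_stage_at_inclusion = factor(NA, levels = levels(stage_g(90))),
    a_stage_at_inclusion = factor(NA, levels = levels(stage_a(1))),
    ever_g5 = FALSE
  )
  if (is.null(series) || !nrow(series)) return(empty)
  gap <- config$min_gap_days
  conf <- c(
    egfr = confirm_date(series$date, !is.na(series$egfr) &
                          series$egfr < config$egfr_below, gap),
    uac  = confirm_date(series$date, !is.na(series$uac) &
                          series$uac >= config$uac_at_least, gap),
    acr  = confirm_date(series$date, !is.na(series$acr) &
                          series$acr >= config$acr_at_least, gap)
  )
  ever_g5 <- any(!is.na(series$egfr) & series$egfr < 15)
  if (all(is.na(conf))) {
    empty$ever_g5 <- ever_g5
    return(empty)
  }
  evidence_date <- min(conf, na.rm = TRUE)
  # tie-break in enum order egfr, uac, acr
  criterion <- names(conf)[which(!is.na(conf) & conf == evidence_date)][1]
  # stage current at confirmation: most recent value at/before evidence date
  at_or_before <- series[series$date <= evidence_date, ]
  last_val <- function(col) {
    v <- at_or_before[[col]][!is.na(at_or_before[[col]])]
    if (length(v)) v[length(v)] else NA_real_
  }
  tibble::tibble(
    ckd_confirmed = TRUE, evidence_date = evidence_date,
    criterion = criterion,
    g_stage_at_inclusion = stage_g(last_val("egfr")),
    a_stage_at_inclusion = stage_a(last_val("acr")),
    ever_g5 = ever_g5
  )
}

#' Detect CKD for every patient in a dataset
#'
#' @param dataset An `emr_dataset`.
#' @param config A [ckd_detection_config()].
#' @return Tibble with one row per patient in the dataset (patients without
#'   renal-function laboratory values appear with `ckd_confirmed = FALSE`),
#'   columns as in [detect_ckd()] plus `patient_id`.
#' @export
detect_ckd_all <- function(dataset, config = ckd_detection_config()) {
  rf <- rf_measurements(dataset)
  found <- rf |>
    tidyr::nest(.by = "patient_id") |>
    dplyr::mutate(res = purrr::map(.data$data, detect_ckd, config = config)) |>
    dplyr::select("patient_id", "res") |>
    tidyr::unnest("res")
  missing <- setdiff(dataset$patients$patient_id, found$patient_id)
  if (length(missing)) {
    blank <- detect_ckd(NULL, config)
    found <- dplyr::bind_rows(
      found,
      dplyr::bind_cols(tibble::tibble(patient_id = missing),
                       blank[rep(1, length(missing)), ]))
  }
  dplyr::arrange(found, .data$patient_id)
}
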