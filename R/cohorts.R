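all_event_dates <- function(dataset) {
  dplyr::bind_rows(
    dataset$encounters[c("patient_id", "date")],
    dataset$prescriptions[c("patient_id", "date")],
    dataset$labs[c("patient_id", "date")],
    dataset$vitals[c("patient_id", "date")]
  )
}

#' First and last observed event dates per patient
#'
#' Observation is operationalised from the data: a patient's first
#' observation is the earliest event of any type (encounter, prescription,
#' lab, vital) and the last contact is the latest. Prescription end dates do
#' not count as contacts.
#'
#' @param dataset An `emr_dataset`.
#' @return Tibble `patient_id`, `first_observation`, `last_contact` (only
#'   patients with at least one event appear).
#' @export
observation_span <- function(dataset) {
  all_event_dates(dataset) |>
    dplyr::summarise(first_observation = min(.data$date),
                     last_contact = max(.data$date),
                     .by = "patient_id")
}

#' Last recorded contact of one patient
#'
#' @param dataset An `emr_dataset`.
#' @param patient_id A patient identifier.
#' @return The maximum event date across all tables, or `NA` if the patient
#'   has no events.
#' @export
last_contact <- function(dataset, patient_id) {
  d <- all_event_dates(dataset)
  d <- d$date[d$patient_id == patient_id]
  if (!length(d)) return(as.Date(NA))
  max(d)
}

#' Build the baseline population
#'
#' Patients with at least one consultation (encounter) recorded during the
#' study window and aged at least 18 years at their first observed event of
#' any type.
#'
#' @param dataset An `emr_dataset`.
#' @return Character vector of qualifying patient ids.
#' @export
build_baseline <- function(dataset) {
  win <- dataset$study_window
  enc <- dataset$encounters
  has_enc <- unique(enc$patient_id[enc$date >= win[1] & enc$date <= win[2]])
  span <- observation_span(dataset)
  span <- dplyr::left_join(span,
                           dataset$patients[c("patient_id", "birth_year")],
                           by = "patient_id")
  span$age_first <- age_at(span$birth_year, span$first_observation)
  adults <- span$patient_id[!is.na(span$age_first) & span$age_first >= 18]
  sort(intersect(has_enc, adults))
}

followup_months <- function(from, to) {
  as.numeric(to - from) / DAYS_PER_MONTH
}

#' Build the renal-function assessment cohort
#'
#' One row per baseline patient carrying at least one predisposing condition
#' (diabetes, hypertension, eCVD) with at least `min_followup_days` between
#' that condition's first evidence and the patient's last recorded contact.
#' Per-condition eligibility flags and index dates are retained so each
#' assessment indicator uses its own condition's index date.
#'
#' @param dataset An `emr_dataset`.
#' @param baseline Patient ids from [build_baseline()].
#' @param timelines Condition timelines from [label_conditions()].
#' @param min_followup_days Follow-up requirement in days (default 548,
#'   i.e. 18 months).
#' @return Tibble: `patient_id`, `gp_id`, `cohort`, per-condition `has_*`
#'   and `eligible_*` flags, per-condition `index_*` dates, `index_date`
#'   (earliest eligible condition evidence), `followup_months` (index to
#'   last contact), `last_contact`.
#' @export
build_rf_cohort <- function(dataset, baseline, timelines,
                            min_followup_days = DAYS_18_MONTHS) {
  span <- observation_span(dataset)
  tl <- timelines[timelines$patient_id %in% baseline, ]
  tl <- dplyr::left_join(tl, span[c("patient_id", "last_contact")],
                         by = "patient_id")
  elig <- function(first) {
    !is.na(first) & !is.na(tl$last_contact) &
      as.numeric(tl$last_contact - first) >= min_followup_days
  }
  out <- tibble::tibble(
    patient_id = tl$patient_id,
    has_diabetes = !is.na(tl$first_diabetes),
    has_hypertension = !is.na(tl$first_hypertension),
    has_ecvd = !is.na(tl$first_ecvd),
    eligible_diabetes = elig(tl$first_diabetes),
    eligible_hypertension = elig(tl$first_hypertension),
    eligible_ecvd = elig(tl$first_ecvd),
    index_diabetes = tl$first_diabetes,
    index_hypertension = tl$first_hypertension,
    index_ecvd = tl$first_ecvd,
    last_contact = tl$last_contact
  )
  out <- out[out$eligible_diabetes | out$eligible_hypertension |
               out$eligible_ecvd, ]
  idx <- pmin(ifelse(out$eligible_diabetes, out$index_diabetes, NA),
              ifelse(out$eligible_hypertension, out$index_hypertension, NA),
              ifelse(out$eligible_ecvd, out$index_ecvd, NA), na.rm = TRUE)
  out$index_date <- as.Date(idx, origin = "1970-01-01")
  out$followup_months <- followup_months(out$index_date, out$last_contact)
  out$cohort <- "rf_assessment"
  out <- dplyr::left_join(out, dataset$patients[c("patient_id", "gp_id")],
                          by = "patient_id")
  dplyr::arrange(out, .data$patient_id)
}

#' Build the CKD care cohort
#'
#' Baseline patients with confirmed laboratory evidence of CKD, excluding
#' anyone ever staged G5 (eGFR < 15 at any time; such patients are presumed
#' referred out of primary care). The index date is the CKD evidence date;
#' KDIGO stages at inclusion and condition flags are attached.
#'
#' @param dataset An `emr_dataset`.
#' @param baseline Patient ids from [build_baseline()].
#' @param evidence Per-patient CKD evidence from [detect_ckd_all()].
#' @param timelines Condition timelines from [label_conditions()].
#' @return Tibble: `patient_id`, `gp_id`, `cohort`, `index_date`,
#'   `followup_months`, `g_stage`, `a_stage`, `criterion`, `has_diabetes`,
#'   `has_hypertension`, `has_ecvd`, `last_contact`.
#' @export
build_ckd_cohort <- function(dataset, baseline, evidence, timelines) {
  ev <- evidence[evidence$ckd_confirmed & !evidence$ever_g5 &
                   evidence$patient_id %in% baseline, ]
  span <- observation_span(dataset)
  out <- ev |>
    dplyr::left_join(span[c("patient_id", "last_contact")], by = "patient_id") |>
    dplyr::left_join(timelines, by = "patient_id") |>
    dplyr::left_join(dataset$patients[c("patient_id", "gp_id")],
                     by = "patient_id")
  tibble::tibble(
    patient_id = out$patient_id,
    gp_id = out$gp_id,
    cohort = "ckd_care",
    index_date = out$evidence_date,
    last_contact = out$last_contact,
    followup_months = followup_months(out$evidence_date, out$last_contact),
    g_stage = out$g_stage_at_inclusion,
    a_stage = out$a_stage_at_inclusion,
    criterion = out$criterion,
    has_diabetes = !is.na(out$first_diabetes),
    has_hypertension = !is.na(out$first_hypertension),
    has_ecvd = !is.na(out$first_ecvd)
  ) |>
    dplyr::arrange(.data$patient_id)
}
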