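#' Quality-indicator evaluation settings
#'
#' Bundles the tunable constants behind the fourteen indicators: ATC code
#' sets, follow-up window lengths in days, treatment-target thresholds, and
#' whether an event on the index date itself counts (default: only events
#' strictly after the index count, so the laboratory measurement that
#' confirms CKD does not double as its own follow-up monitoring).
#'
#' @param atc_raas ATC prefixes counted as RAAS inhibitors.
#' @param atc_statin ATC prefixes counted as statins (plain and combination).
#' @param atc_nsaid ATC prefixes counted as NSAIDs.
#' @param atc_nsaid_exclude ATC prefixes never counted as NSAIDs
#'   (acetylsalicylic acid and related).
#' @param days_18m,days_12m Window lengths in days for the 18- and 12-month
#'   follow-up requirements.
#' @param count_index_date If `TRUE`, events dated exactly at the index date
#'   qualify for window-based indicators.
#' @param statin_age Inclusive age range at index for the statin indicator.
#' @param bp_target,bp_target_diabetes `c(systolic, diastolic)` targets; the
#'   latest complete reading must be strictly below both components.
#' @param bmi_range Closed BMI target interval (kg/m^2).
#' @return List of class `qi_config`.
#' @export
qi_config <- function(atc_raas = "C09",
                      atc_statin = c("C10AA", "C10B"),
                      atc_nsaid = "M01A",
                      atc_nsaid_exclude = c("M01BA", "B01AC06", "N02BA01"),
                      days_18m = DAYS_18_MONTHS,
                      days_12m = DAYS_12_MONTHS,
                      count_index_date = FALSE,
                      statin_age = c(50, 80),
                      bp_target = c(140, 90),
                      bp_target_diabetes = c(130, 80),
                      bmi_range = c(20, 25)) {
  structure(list(atc_raas = atc_raas, atc_statin = atc_statin,
                 atc_nsaid = atc_nsaid, atc_nsaid_exclude = atc_nsaid_exclude,
                 days_18m = days_18m, days_12m = days_12m,
                 count_index_date = count_index_date, statin_age = statin_age,
                 bp_target = bp_target,
                 bp_target_diabetes = bp_target_diabetes,
                 bmi_range = bmi_range),
            class = "qi_config")
}

#' The fourteen quality-indicator definitions
#'
#' @return Tibble with `qi_id`, `category`, `description` (shorthand
#'   "outcome; denominator (window months)") and `window_months`.
#' @export
qi_definitions <- function() {
  tibble::tibble(
    qi_id = 1:14,
    category = c(rep("assessment", 3), rep("monitoring", 5),
                 rep("medication", 3), rep("treatment_target", 3)),
    description = c(
      "RF; diabetes (18)", "RF; hypertension (18)", "RF; eCVD (18)",
      "eGFR/SCr; G1-4 (18)", "ACR/UAC; G1-4 (18)", "RF+BP; G2-4 (18)",
      "RF+BP+CBC+chem; G3a-4 (18)", "RF+BP+CBC+chem+MBD; G3b-4 (18)",
      "RAAS inhibitor; G1-4 (12)", "Statin; G1-4, 50-80 years (12)",
      "Withheld NSAID; G2-3b (12)",
      "Latest BP < 140/90 mmHg; G1-4", "Latest BP < 130/80 mmHg; G1-4, diabetes",
      "Latest BMI 20-25 kg/m2; G1-4"),
    window_months = c(rep(18L, 8), rep(12L, 3), rep(NA_integer_, 3))
  )
}

stage_in <- function(g_stage, from, to) {
  lv <- c("G1", "G2", "G3a", "G3b", "G4", "G5")
  i <- match(as.character(g_stage), lv)
  !is.na(i) & i >= match(from, lv) & i <= match(to, lv)
}

# TRUE per member when the patient has >= 1 qualifying event date strictly
# inside the member's window (index, index + window_days); with
# count_index_date the lower edge closes to [index, ...).
window_hit <- function(events, members, window_days, count_index) {
  if (!nrow(events) || !nrow(members)) return(rep(FALSE, nrow(members)))
  j <- dplyr::inner_join(events,
                         members[c("patient_id", "index_date")],
                         by = "patient_id", relationship = "many-to-many")
  lower_ok <- if (count_index) j$date >= j$index_date else j$date > j$index_date
  hit <- unique(j$patient_id[lower_ok &
                               as.numeric(j$date - j$index_date) < window_days])
  members$patient_id %in% hit
}

# active-prescription semantics: the prescription start falls in the window,
# or its [start, end] interval overlaps the window when an end date exists
rx_window_hit <- function(rx, members, window_days, count_index) {
  if (!nrow(rx) || !nrow(members)) return(rep(FALSE, nrow(members)))
  started <- window_hit(rx[c("patient_id", "date")], members, window_days,
                        count_index)
  rx_end <- rx[!is.na(rx$end_date), c("patient_id", "date", "end_date")]
  overlap <- rep(FALSE, nrow(members))
  if (nrow(rx_end)) {
    j <- dplyr::inner_join(rx_end, members[c("patient_id", "index_date")],
                           by = "patient_id", relationship = "many-to-many")
    ok <- j$date <= j$index_date & j$end_date > j$index_date
    overlap <- members$patient_id %in% unique(j$patient_id[ok])
  }
  started | overlap
}

lab_events <- function(dataset, analytes) {
  labs <- dataset$labs
  labs[labs$analyte %in% analytes, c("patient_id", "date")]
}

bp_events <- function(dataset, complete = FALSE) {
  v <- dataset$vitals
  keep <- if (complete) !is.na(v$systolic_bp) & !is.na(v$diastolic_bp)
          else !is.na(v$systolic_bp) | !is.na(v$diastolic_bp)
  v[keep, c("patient_id", "date", "systolic_bp", "diastolic_bp")]
}

bmi_events <- function(dataset) {
  v <- dataset$vitals
  bmi <- ifelse(!is.na(v$bmi), v$bmi,
                ifelse(!is.na(v$weight) & !is.na(v$height),
                       v$weight / (v$height / 100)^2, NA_real_))
  out <- v[c("patient_id", "date")]
  out$bmi <- bmi
  out[!is.na(out$bmi), ]
}

atc_events <- function(dataset, include, exclude = character()) {
  rx <- dataset$prescriptions
  keep <- prefix_match(rx$atc_code, include)
  if (length(exclude)) keep <- keep & !prefix_match(rx$atc_code, exclude)
  rx[keep, c("patient_id", "date", "end_date")]
}

# latest value strictly after index among `events` (col `cols`); returns a
# tibble aligned with members (NA when no qualifying measurement)
latest_after_index <- function(events, members, cols) {
  out <- members["patient_id"]
  for (cl in cols) out[[cl]] <- NA_real_
  if (!nrow(events) || !nrow(members)) return(out)
  j <- dplyr::inner_join(events, members[c("patient_id", "index_date")],
                         by = "patient_id", relationship = "many-to-many")
  j <- j[j$date > j$index_date, ]
  if (!nrow(j)) return(out)
  j <- j |>
    dplyr::arrange(.data$patient_id, .data$date) |>
    dplyr::slice_tail(n = 1, by = "patient_id")
  m <- match(out$patient_id, j$patient_id)
  for (cl in cols) out[[cl]] <- j[[cl]][m]
  out
}

rf_analytes <- function() c("serum_creatinine", "egfr", "acr", "uac")

#' Evaluate one quality indicator
#'
#' Implements one of the fourteen indicator definitions: selects the
#' denominator from the appropriate cohort (stage range, follow-up
#' requirement, condition or age restriction), evaluates the numerator rule
#' (event occurrence in the follow-up window, prescription
#' presence/absence, or latest-measurement target), and returns per-patient
#' flags plus the achievement rate.
#'
#' @param qi_id Integer 1-14.
#' @param cohorts List with elements `rf` ([build_rf_cohort()]) and `ckd`
#'   ([build_ckd_cohort()]).
#' @param dataset The `emr_dataset`.
#' @param config A [qi_config()].
#' @return Object of class `qi_result`: `qi_id`, `category`, `description`,
#'   `flags` (tibble `patient_id`, `gp_id`, `in_denominator`, `achieved`),
#'   `n_denominator`, `n_numerator`, `achievement_rate` (percent).
#' @export
evaluate_qi <- function(qi_id, cohorts, dataset, config = qi_config()) {
  if (!is.numeric(qi_id) || length(qi_id) != 1L || !qi_id %in% 1:14) {
    abort_ckdqi("unknown qi_id: %s", paste(qi_id, collapse = ","))
  }
  qi_id <- as.integer(qi_id)
  def <- qi_definitions()[qi_id, ]
  ci <- config$count_index_date
  rf_cohort <- cohorts$rf
  ckd <- cohorts$ckd

  if (qi_id <= 3L) {
    cond <- c("diabetes", "hypertension", "ecvd")[qi_id]
    members <- rf_cohort
    members$index_date <- members[[paste0("index_", cond)]]
    in_den <- members[[paste0("eligible_", cond)]]
    den <- members[in_den, ]
    ach <- window_hit(lab_events(dataset, rf_analytes()), den,
                      config$days_18m, ci)
  } else {
    fu_days <- as.numeric(ckd$last_contact - ckd$index_date)
    in_den <- switch(as.character(qi_id),
      "4" = stage_in(ckd$g_stage, "G1", "G4") & fu_days >= config$days_18m,
      "5" = stage_in(ckd$g_stage, "G1", "G4") & fu_days >= config$days_18m,
      "6" = stage_in(ckd$g_stage, "G2", "G4") & fu_days >= config$days_18m,
      "7" = stage_in(ckd$g_stage, "G3a", "G4") & fu_days >= config$days_18m,
      "8" = stage_in(ckd$g_stage, "G3b", "G4") & fu_days >= config$days_18m,
      "9" = stage_in(ckd$g_stage, "G1", "G4") & fu_days >= config$days_12m,
      "10" = {
        age_idx <- age_at(
          dataset$patients$birth_year[match(ckd$patient_id,
                                            dataset$patients$patient_id)],
          ckd$index_date)
        stage_in(ckd$g_stage, "G1", "G4") & fu_days >= config$days_12m &
          !is.na(age_idx) & age_idx >= config$statin_age[1] &
          age_idx <= config$statin_age[2]
      },
      "11" = stage_in(ckd$g_stage, "G2", "G3b") & fu_days >= config$days_12m,
      "12" = ,
      "13" = ,
      "14" = stage_in(ckd$g_stage, "G1", "G4")
    )
    members <- ckd
    den <- members[in_den, ]
    ach <- switch(as.character(qi_id),
      "4" = window_hit(lab_events(dataset, c("serum_creatinine", "egfr")),
                       den, config$days_18m, ci),
      "5" = window_hit(lab_events(dataset, c("acr", "uac")), den,
                       config$days_18m, ci),
      "6" = window_hit(lab_events(dataset, rf_analytes()), den,
                       config$days_18m, ci) &
            window_hit(bp_events(dataset)[c("patient_id", "date")], den,
                       config$days_18m, ci),
      "7" = window_hit(lab_events(dataset, rf_analytes()), den,
                       config$days_18m, ci) &
            window_hit(bp_events(dataset)[c("patient_id", "date")], den,
                       config$days_18m, ci) &
            window_hit(lab_events(dataset, "hemoglobin"), den,
                       config$days_18m, ci) &
            window_hit(lab_events(dataset, c("urea", "sodium", "potassium")),
                       den, config$days_18m, ci),
      "8" = window_hit(lab_events(dataset, rf_analytes()), den,
                       config$days_18m, ci) &
            window_hit(bp_events(dataset)[c("patient_id", "date")], den,
                       config$days_18m, ci) &
            window_hit(lab_events(dataset, "hemoglobin"), den,
                       config$days_18m, ci) &
            window_hit(lab_events(dataset, c("urea", "sodium", "potassium")),
                       den, config$days_18m, ci) &
            window_hit(lab_events(dataset,
                                  c("alkaline_phosphatase", "calcium",
                                    "phosphate", "parathyroid_hormone")),
                       den, config$days_18m, ci),
      "9" = rx_window_hit(atc_events(dataset, config$atc_raas), den,
                          config$days_12m, ci),
      "10" = rx_window_hit(atc_events(dataset, config$atc_statin), den,
                           config$days_12m, ci),
      "11" = !rx_window_hit(atc_events(dataset, config$atc_nsaid,
                                       config$atc_nsaid_exclude),
                            den, config$days_12m, ci),
      "12" = {
        bp <- latest_after_index(bp_events(dataset, complete = TRUE), den,
                                 c("systolic_bp", "diastolic_bp"))
        !is.na(bp$systolic_bp) & bp$systolic_bp < config$bp_target[1] &
          bp$diastolic_bp < config$bp_target[2]
      },
      "13" = {
        bp <- latest_after_index(bp_events(dataset, complete = TRUE), den,
                                 c("systolic_bp", "diastolic_bp"))
        !is.na(bp$systolic_bp) &
          bp$systolic_bp < config$bp_target_diabetes[1] &
          bp$diastolic_bp < config$bp_target_diabetes[2]
      },
      "14" = {
        bmi <- latest_after_index(bmi_events(dataset), den, "bmi")
        !is.na(bmi$bmi) & bmi$bmi >= config$bmi_range[1] &
          bmi$bmi <= config$bmi_range[2]
      }
    )
    # treatment-target denominators additionally require a qualifying
    # measurement after the index date
    if (qi_id %in% 12:14) {
      ev <- if (qi_id == 14L) bmi_events(dataset)[c("patient_id", "date")]
            else bp_events(dataset, complete = TRUE)[c("patient_id", "date")]
      has_meas <- rep(FALSE, nrow(den))
      if (nrow(ev) && nrow(den)) {
        j <- dplyr::inner_join(ev, den[c("patient_id", "index_date")],
                               by = "patient_id",
                               relationship = "many-to-many")
        has_meas <- den$patient_id %in%
          unique(j$patient_id[j$date > j$index_date])
      }
      if (qi_id == 13L) has_meas <- has_meas & den$has_diabetes
      ach <- ach[has_meas]
      den <- den[has_meas, ]
      in_den[in_den] <- has_meas
    }
  }

  flags <- tibble::tibble(
    patient_id = members$patient_id,
    gp_id = members$gp_id,
    in_denominator = in_den,
    achieved = NA
  )
  flags$achieved[in_den] <- ach
  n_den <- sum(in_den)
  n_num <- sum(ach)
  structure(list(
    qi_id = qi_id, category = def$category, description = def$description,
    flags = flags, n_denominator = n_den, n_numerator = n_num,
    achievement_rate = if (n_den > 0) 100 * n_num / n_den else NA_real_
  ), class = "qi_result")
}

#' Evaluate all fourteen quality indicators
#'
#' @inheritParams evaluate_qi
#' @return List with `results` (list of [evaluate_qi()] objects keyed
#'   `qi1`..`qi14`) and `summary` (tibble `category`, `qi_id`,
#'   `description`, `n_denominator`, `n_numerator`, `achievement_rate`).
#' @export
evaluate_all <- function(cohorts, dataset, config = qi_config()) {
  results <- lapply(1:14, evaluate_qi, cohorts = cohorts, dataset = dataset,
                    config = config)
  names(results) <- paste0("qi", 1:14)
  summary <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(category = r$category, qi_id = r$qi_id,
                   description = r$description,
                   n_denominator = r$n_denominator,
                   n_numerator = r$n_numerator,
                   achievement_rate = r$achievement_rate)
  }))
  list(results = results, summary = summary)
}

#' @export
print.qi_result <- function(x, ...) {
  cat(sprintf("<qi_result> QI %d [%s] %s\n", x$qi_id, x$category,
              x$description))
  cat(sprintf("  denominator %d, numerator %d, achievement %.1f%%\n",
              x$n_denominator, x$n_numerator, x$achievement_rate))
  invisible(x)
}
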