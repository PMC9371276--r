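#' Default condition identification rules
#'
#' Declarative criteria for labelling diabetes, hypertension and established
#' cardiovascular disease (eCVD) from encounters (ICPC-2 code prefixes),
#' prescriptions (ATC code prefixes), laboratory values and vital signs.
#' The defaults are documented approximations of commonly used EMR
#' operationalisations; studies with their own validated code lists should
#' supply them via [load_rule_set()] — the engine is config-first.
#'
#' * diabetes: ICPC-2 T89/T90, ATC A10*, HbA1c >= 6.5 %
#' * hypertension: ICPC-2 K86/K87, ATC C02*/C03*/C07*/C08*/C09*, and at
#'   least two blood-pressure readings >= 140/90 mmHg (a reading qualifies
#'   when either component is at/above its threshold)
#' * eCVD: ICPC-2 K74, K75, K76, K89, K90, K91, K92
#'
#' @return A `condition_rule_set` list keyed by condition.
#' @export
default_condition_rules <- function() {
  rules <- list(
    diabetes = list(
      icpc2_codes = c("T89", "T90"),
      atc_codes = "A10",
      lab_criteria = list(
        list(analyte = "hba1c", comparator = ">=", threshold = 6.5)
      ),
      vital_criteria = list()
    ),
    hypertension = list(
      icpc2_codes = c("K86", "K87"),
      atc_codes = c("C02", "C03", "C07", "C08", "C09"),
      lab_criteria = list(),
      vital_criteria = list(
        list(fields = list(systolic_bp = 140, diastolic_bp = 90),
             comparator = ">=", min_occurrences = 2L)
      )
    ),
    ecvd = list(
      icpc2_codes = c("K74", "K75", "K76", "K89", "K90", "K91", "K92"),
      atc_codes = character(),
      lab_criteria = list(),
      vital_criteria = list()
    )
  )
  structure(rules, class = "condition_rule_set")
}

validate_rule_set <- function(rules) {
  known <- c("diabetes", "hypertension", "ecvd")
  unknown <- setdiff(names(rules), known)
  if (length(unknown)) {
    abort_ckdqi("unknown condition key(s): %s", paste(unknown, collapse = ", "))
  }
  for (cond in names(rules)) {
    r <- rules[[cond]]
    for (code in r$icpc2_codes) {
      if (!grepl("^[A-Z][0-9]{0,2}$", code)) {
        abort_ckdqi("invalid ICPC-2 prefix '%s' for %s", code, cond)
      }
    }
    for (code in r$atc_codes) {
      if (!grepl("^[A-V][0-9]{0,2}[A-Z]{0,2}[0-9]{0,2}$", code)) {
        abort_ckdqi("invalid ATC prefix '%s' for %s", code, cond)
      }
    }
    for (cr in r$lab_criteria) {
      if (!cr$analyte %in% names(analyte_units())) {
        abort_ckdqi("unknown analyte '%s' in %s rule", cr$analyte, cond)
      }
      if (!cr$comparator %in% c(">=", ">", "<=", "<")) {
        abort_ckdqi("invalid comparator in %s rule", cond)
      }
      if (!is_scalar_number(cr$threshold) || cr$threshold <= 0) {
        abort_ckdqi("lab threshold must be positive in %s rule", cond)
      }
    }
    for (cr in r$vital_criteria) {
      if (!length(cr$fields)) abort_ckdqi("vital criterion without fields in %s", cond)
      bad <- setdiff(names(cr$fields),
                     c("systolic_bp", "diastolic_bp", "bmi", "weight", "height"))
      if (length(bad)) abort_ckdqi("unknown vital field(s) in %s rule", cond)
      if (any(unlist(cr$fields) <= 0)) {
        abort_ckdqi("vital threshold must be positive in %s rule", cond)
      }
      if (!cr$comparator %in% c(">=", ">", "<=", "<")) {
        abort_ckdqi("invalid comparator in %s rule", cond)
      }
      if ((cr$min_occurrences %||% 1L) < 1L) {
        abort_ckdqi("min_occurrences must be >= 1 in %s rule", cond)
      }
    }
  }
  invisible(TRUE)
}

#' Load a condition rule set
#'
#' @param config `NULL` (defaults), a path to a YAML file, or a list. Lists
#'   and YAML contents are merged over [default_condition_rules()]:
#'   supplying a field for a condition replaces that field.
#' @return A validated `condition_rule_set`.
#' @export
load_rule_set <- function(config = NULL) {
  rules <- unclass(default_condition_rules())
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) abort_ckdqi("rule config must be a list or YAML path")
    unknown <- setdiff(names(config), names(rules))
    if (length(unknown)) {
      abort_ckdqi("unknown condition key(s): %s", paste(unknown, collapse = ", "))
    }
    for (cond in names(config)) {
      for (field in names(config[[cond]])) {
        rules[[cond]][[field]] <- config[[cond]][[field]]
      }
    }
  }
  rules <- structure(rules, class = "condition_rule_set")
  validate_rule_set(rules)
  rules
}

compare_vals <- function(x, comparator, threshold) {
  switch(comparator,
         ">=" = x >= threshold, ">" = x > threshold,
         "<=" = x <= threshold, "<" = x < threshold)
}

prefix_match <- function(codes, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(codes)))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit & !is.na(codes)
}

# earliest date a single condition's criteria fire for one patient's events
first_condition_date <- function(rule, enc, rx, labs, vitals) {
  dates <- as.Date(character())
  if (length(rule$icpc2_codes) && nrow(enc)) {
    hit <- prefix_match(enc$icpc2_code, rule$icpc2_codes)
    if (any(hit)) dates <- c(dates, min(enc$date[hit]))
  }
  if (length(rule$atc_codes) && nrow(rx)) {
    hit <- prefix_match(rx$atc_code, rule$atc_codes)
    if (any(hit)) dates <- c(dates, min(rx$date[hit]))
  }
  for (cr in rule$lab_criteria) {
    if (!nrow(labs)) next
    hit <- labs$analyte == cr$analyte &
      compare_vals(labs$value, cr$comparator, cr$threshold)
    if (any(hit)) dates <- c(dates, min(labs$date[hit]))
  }
  for (cr in rule$vital_criteria) {
    if (!nrow(vitals)) next
    qual <- rep(FALSE, nrow(vitals))
    for (f in names(cr$fields)) {
      v <- vitals[[f]]
      qual <- qual | (!is.na(v) & compare_vals(v, cr$comparator, cr$fields[[f]]))
    }
    k <- cr$min_occurrences %||% 1L
    d <- sort(vitals$date[qual])
    # the condition dates from the day the occurrence count is reached
    if (length(d) >= k) dates <- c(dates, d[k])
  }
  if (length(dates)) min(dates) else as.Date(NA)
}

#' Label predisposing conditions with first-evidence dates
#'
#' Scans each patient's encounters, prescriptions, laboratory values and
#' vitals against a rule set; the first-evidence date per condition is the
#' earliest date any single criterion fires (for multi-occurrence vital
#' criteria, the date the required count is reached). Conditions are treated
#' as chronic: once acquired, a label persists.
#'
#' @param dataset An `emr_dataset`.
#' @param rules A `condition_rule_set` from [load_rule_set()].
#' @return Tibble with one row per patient: `patient_id`, `first_diabetes`,
#'   `first_hypertension`, `first_ecvd` (`NA` when never observed).
#' @export
label_conditions <- function(dataset, rules = default_condition_rules()) {
  stopifnot(inherits(rules, "condition_rule_set"))
  ids <- dataset$patients$patient_id
  enc_s <- split(dataset$encounters, dataset$encounters$patient_id)
  rx_s <- split(dataset$prescriptions, dataset$prescriptions$patient_id)
  lab_s <- split(dataset$labs, dataset$labs$patient_id)
  vit_s <- split(dataset$vitals, dataset$vitals$patient_id)
  empty_enc <- dataset$encounters[0, ]; empty_rx <- dataset$prescriptions[0, ]
  empty_lab <- dataset$labs[0, ]; empty_vit <- dataset$vitals[0, ]
  res <- lapply(ids, function(id) {
    enc <- enc_s[[id]] %||% empty_enc
    rx <- rx_s[[id]] %||% empty_rx
    labs <- lab_s[[id]] %||% empty_lab
    vit <- vit_s[[id]] %||% empty_vit
    vapply(c("diabetes", "hypertension", "ecvd"), function(cond) {
      as.numeric(first_condition_date(rules[[cond]], enc, rx, labs, vit))
    }, numeric(1))
  })
  if (!length(res)) {
    return(tibble::tibble(patient_id = character(),
                          first_diabetes = as.Date(character()),
                          first_hypertension = as.Date(character()),
                          first_ecvd = as.Date(character())))
  }
  m <- do.call(rbind, res)
  tibble::tibble(
    patient_id = ids,
    first_diabetes = as.Date(m[, "diabetes"], origin = "1970-01-01"),
    first_hypertension = as.Date(m[, "hypertension"], origin = "1970-01-01"),
    first_ecvd = as.Date(m[, "ecvd"], origin = "1970-01-01")
  )
}
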