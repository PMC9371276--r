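#' Canonical laboratory analytes and units
#'
#' The data model stores every laboratory value in one canonical unit per
#' analyte. Ingestion converts declared source units (e.g. creatinine in
#' mg/dL) into these; rows in unknown units are rejected and counted.
#'
#' @return Named character vector mapping analyte name to canonical unit.
#' @export
analyte_units <- function() {
  c(
    serum_creatinine     = "umol/l",
    egfr                 = "ml/min/1.73m2",
    acr                  = "mg/mmol",
    uac                  = "mg/l",
    hemoglobin           = "g/l",
    sodium               = "mmol/l",
    potassium            = "mmol/l",
    urea                 = "mmol/l",
    alkaline_phosphatase = "U/l",
    calcium              = "mmol/l",
    phosphate            = "mmol/l",
    parathyroid_hormone  = "ng/l",
    hba1c                = "%",
    ldl                  = "mmol/l",
    total_cholesterol    = "mmol/l"
  )
}

# Multiplicative conversions into the canonical unit, keyed by
# analyte -> normalised source unit. Canonical units convert with factor 1.
unit_conversions <- function() {
  list(
    serum_creatinine = c("umol/l" = 1, "mg/dl" = 88.42),
    egfr             = c("ml/min/1.73m2" = 1),
    acr              = c("mg/mmol" = 1, "mg/g" = 0.113),
    uac              = c("mg/l" = 1),
    hemoglobin       = c("g/l" = 1, "g/dl" = 10),
    sodium           = c("mmol/l" = 1),
    potassium        = c("mmol/l" = 1),
    urea             = c("mmol/l" = 1),
    alkaline_phosphatase = c("u/l" = 1),
    calcium          = c("mmol/l" = 1),
    phosphate        = c("mmol/l" = 1),
    parathyroid_hormone = c("ng/l" = 1, "pg/ml" = 1),
    hba1c            = c("%" = 1),
    ldl              = c("mmol/l" = 1),
    total_cholesterol = c("mmol/l" = 1)
  )
}

normalise_unit <- function(u) {
  u <- tolower(gsub("[[:space:]]", "", as.character(u)))
  u <- gsub("µ|μ", "u", u)  # micro signs -> "u"
  u <- gsub("1\\.73\\s*m\\^?2", "1.73m2", u)
  u
}

ATC_PATTERN <- "^[A-V][0-9]{2}[A-Z]{0,2}[0-9]{0,2}$"

#' Ingestion configuration
#'
#' @param study_window Length-2 Date vector (start, end). Events dated after
#'   the window end are rejected at ingestion.
#' @param default_units Named list analyte -> unit assumed when the lab table
#'   carries no unit column (defaults to the canonical units).
#' @return A list of class `ckdqi_ingestion_config`.
#' @export
ingestion_config <- function(study_window = as.Date(c("2013-01-01", "2019-12-31")),
                             default_units = as.list(analyte_units())) {
  study_window <- as_date_safe(study_window)
  if (length(study_window) != 2L || any(is.na(study_window)) ||
      study_window[1] > study_window[2]) {
    abort_ckdqi("study_window must be two valid dates with start <= end")
  }
  structure(list(study_window = study_window, default_units = default_units),
            class = "ckdqi_ingestion_config")
}

emr_table_names <- function() {
  c("patients", "gps", "encounters", "prescriptions", "labs", "vitals")
}

required_columns <- function() {
  list(
    patients      = c("patient_id", "gp_id", "gender", "birth_year"),
    gps           = c("gp_id", "gender", "birth_year", "urban_location"),
    encounters    = c("patient_id", "date"),
    prescriptions = c("patient_id", "date", "atc_code"),
    labs          = c("patient_id", "date", "analyte", "value"),
    vitals        = c("patient_id", "date")
  )
}

#' Construct a validated EMR dataset
#'
#' Bundles the six linked tables (patients, GPs, encounters, prescriptions,
#' labs, vitals) with the study window. Invariants are enforced: unique ids,
#' resolving foreign keys, positive lab values in canonical units, and no
#' event dated after the study window end.
#'
#' @param patients,gps,encounters,prescriptions,labs,vitals Data frames.
#' @param study_window Length-2 Date vector.
#' @return An object of class `emr_dataset`.
#' @export
emr_dataset <- function(patients, gps, encounters, prescriptions, labs, vitals,
                        study_window = as.Date(c("2013-01-01", "2019-12-31"))) {
  x <- structure(
    list(
      patients      = tibble::as_tibble(patients),
      gps           = tibble::as_tibble(gps),
      encounters    = tibble::as_tibble(encounters),
      prescriptions = tibble::as_tibble(prescriptions),
      labs          = tibble::as_tibble(labs),
      vitals        = tibble::as_tibble(vitals),
      study_window  = as_date_safe(study_window)
    ),
    class = "emr_dataset"
  )
  validate_emr_dataset(x)
  x
}

#' Validate an EMR dataset's invariants
#'
#' @param x An `emr_dataset`.
#' @return Invisibly `TRUE`; aborts with a descriptive error otherwise.
#' @export
validate_emr_dataset <- function(x) {
  if (!inherits(x, "emr_dataset")) abort_ckdqi("not an emr_dataset")
  req <- required_columns()
  for (tab in emr_table_names()) {
    missing <- setdiff(req[[tab]], names(x[[tab]]))
    if (length(missing)) {
      abort_ckdqi("table '%s' lacks required column(s): %s",
                  tab, paste(missing, collapse = ", "))
    }
  }
  if (anyDuplicated(x$patients$patient_id)) abort_ckdqi("duplicate patient_id")
  if (anyDuplicated(x$gps$gp_id)) abort_ckdqi("duplicate gp_id")
  if (!all(x$patients$gp_id %in% x$gps$gp_id)) {
    abort_ckdqi("patients reference unknown gp_id")
  }
  ids <- x$patients$patient_id
  for (tab in c("encounters", "prescriptions", "labs", "vitals")) {
    if (!all(x[[tab]]$patient_id %in% ids)) {
      abort_ckdqi("table '%s' references unknown patient_id", tab)
    }
    if (nrow(x[[tab]]) && any(is.na(x[[tab]]$date))) {
      abort_ckdqi("table '%s' contains missing dates", tab)
    }
    if (nrow(x[[tab]]) && any(x[[tab]]$date > x$study_window[2])) {
      abort_ckdqi("table '%s' has events after the study window end", tab)
    }
  }
  if (nrow(x$labs)) {
    bad <- !x$labs$analyte %in% names(analyte_units())
    if (any(bad)) abort_ckdqi("labs contain unknown analyte(s)")
    if (any(!is.finite(x$labs$value) | x$labs$value <= 0)) {
      abort_ckdqi("labs contain non-positive values")
    }
  }
  invisible(TRUE)
}

reject <- function(report, table, reason, n) {
  if (n > 0) {
    report[[table]]$rejected <- report[[table]]$rejected + n
    report[[table]]$reasons[[reason]] <-
      (report[[table]]$reasons[[reason]] %||% 0L) + n
  }
  report
}

#' Read and validate the six delimited EMR tables
#'
#' Reads CSV/TSV exports, applies unit conversions into canonical units,
#' drops rows that fail validation (counting them per table and reason), and
#' returns a validated [emr_dataset()]. A missing required column is a hard
#' error naming the file and column; a malformed row (unparseable date,
#' unknown analyte or unit, non-positive value, ATC grammar violation,
#' unresolvable foreign key, event after the study window end) is rejected
#' and counted.
#'
#' @param paths Named list/vector of file paths with names `patients`, `gps`,
#'   `encounters`, `prescriptions`, `labs`, `vitals`.
#' @param config An [ingestion_config()].
#' @return An `emr_dataset`; the ingestion report is attached as attribute
#'   `"ingestion_report"` and retrievable with [ingestion_report()].
#' @export
read_emr_tables <- function(paths, config = ingestion_config()) {
  stopifnot(inherits(config, "ckdqi_ingestion_config"))
  missing_tabs <- setdiff(emr_table_names(), names(paths))
  if (length(missing_tabs)) {
    abort_ckdqi("paths must name all six tables; missing: %s",
                paste(missing_tabs, collapse = ", "))
  }
  raw <- list()
  for (tab in emr_table_names()) {
    path <- paths[[tab]]
    if (!file.exists(path)) abort_ckdqi("file not found for table '%s': %s", tab, path)
    delim <- if (grepl("\\.tsv$", path)) "\t" else ","
    raw[[tab]] <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                                    col_types = readr::cols(.default = readr::col_character()),
                                    progress = FALSE)
    missing <- setdiff(required_columns()[[tab]], names(raw[[tab]]))
    if (length(missing)) {
      abort_ckdqi("file '%s' (table '%s') lacks required column(s): %s",
                  path, tab, paste(missing, collapse = ", "))
    }
  }

  report <- lapply(raw, function(d) list(rows_in = nrow(d), rejected = 0L,
                                         reasons = list()))
  win_end <- config$study_window[2]

  drop_bad_dates <- function(d, tab, col = "date", required = TRUE) {
    d[[col]] <- as_date_safe(d[[col]])
    if (required) {
      bad <- is.na(d[[col]])
      report <<- reject(report, tab, paste0("unparseable_", col), sum(bad))
      d <- d[!bad, , drop = FALSE]
      late <- d[[col]] > win_end
      report <<- reject(report, tab, "after_window_end", sum(late))
      d <- d[!late, , drop = FALSE]
    }
    d
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  # GPs ----
  gps <- raw$gps
  gps$gender <- ifelse(gps$gender %in% c("female", "male"), gps$gender, "unknown")
  gps$birth_year <- num(gps$birth_year)
  gps$urban_location <- dplyr::case_when(
    tolower(gps$urban_location) %in% c("true", "1", "yes") ~ TRUE,
    tolower(gps$urban_location) %in% c("false", "0", "no") ~ FALSE,
    TRUE ~ NA
  )
  dup <- duplicated(gps$gp_id)
  report <- reject(report, "gps", "duplicate_id", sum(dup))
  gps <- gps[!dup, , drop = FALSE]

  # Patients ----
  pats <- raw$patients
  bad_gender <- !pats$gender %in% c("female", "male", "other")
  report <- reject(report, "patients", "invalid_gender", sum(bad_gender))
  pats <- pats[!bad_gender, , drop = FALSE]
  pats$birth_year <- num(pats$birth_year)
  bad_by <- is.na(pats$birth_year)
  report <- reject(report, "patients", "missing_birth_year", sum(bad_by))
  pats <- pats[!bad_by, , drop = FALSE]
  bad_fk <- !pats$gp_id %in% gps$gp_id
  report <- reject(report, "patients", "unknown_gp", sum(bad_fk))
  pats <- pats[!bad_fk, , drop = FALSE]
  dup <- duplicated(pats$patient_id)
  report <- reject(report, "patients", "duplicate_id", sum(dup))
  pats <- pats[!dup, , drop = FALSE]

  known_pat <- function(d, tab) {
    bad <- !d$patient_id %in% pats$patient_id
    report <<- reject(report, tab, "unknown_patient", sum(bad))
    d[!bad, , drop = FALSE]
  }

  # Encounters ----
  enc <- drop_bad_dates(raw$encounters, "encounters")
  enc <- known_pat(enc, "encounters")
  if (!"icpc2_code" %in% names(enc)) enc$icpc2_code <- NA_character_
  enc$icpc2_code[enc$icpc2_code == ""] <- NA_character_

  # Prescriptions ----
  rx <- drop_bad_dates(raw$prescriptions, "prescriptions")
  rx <- known_pat(rx, "prescriptions")
  bad_atc <- is.na(rx$atc_code) | !grepl(ATC_PATTERN, rx$atc_code)
  report <- reject(report, "prescriptions", "invalid_atc", sum(bad_atc))
  rx <- rx[!bad_atc, , drop = FALSE]
  if (!"end_date" %in% names(rx)) rx$end_date <- NA_character_
  rx$end_date <- as_date_safe(rx$end_date)

  # Labs ----
  labs <- drop_bad_dates(raw$labs, "labs")
  labs <- known_pat(labs, "labs")
  bad_an <- !labs$analyte %in% names(analyte_units())
  report <- reject(report, "labs", "unknown_analyte", sum(bad_an))
  labs <- labs[!bad_an, , drop = FALSE]
  labs$value <- num(labs$value)
  bad_val <- !is.finite(labs$value) | labs$value <= 0
  report <- reject(report, "labs", "nonpositive_value", sum(bad_val))
  labs <- labs[!bad_val, , drop = FALSE]
  if (!"unit" %in% names(labs)) labs$unit <- NA_character_
  default_units <- config$default_units
  labs$unit <- ifelse(is.na(labs$unit) | labs$unit == "",
                      unlist(default_units[labs$analyte], use.names = FALSE),
                      labs$unit)
  conv <- unit_conversions()
  lookup <- unlist(lapply(names(conv), function(a) {
    setNames(conv[[a]], paste(a, normalise_unit(names(conv[[a]])), sep = "|"))
  }))
  fac <- unname(lookup[paste(labs$analyte, normalise_unit(labs$unit), sep = "|")])
  bad_unit <- is.na(fac)
  report <- reject(report, "labs", "unknown_unit", sum(bad_unit))
  labs <- labs[!bad_unit, , drop = FALSE]
  labs$value <- labs$value * fac[!bad_unit]
  labs$unit <- unname(analyte_units()[labs$analyte])

  # Vitals ----
  vit <- drop_bad_dates(raw$vitals, "vitals")
  vit <- known_pat(vit, "vitals")
  for (col in c("systolic_bp", "diastolic_bp", "bmi", "weight", "height")) {
    if (!col %in% names(vit)) vit[[col]] <- NA_character_
    vit[[col]] <- num(vit[[col]])
    vit[[col]][!is.na(vit[[col]]) & vit[[col]] <= 0] <- NA_real_
  }
  empty <- rowSums(!is.na(vit[c("systolic_bp", "diastolic_bp", "bmi",
                                "weight", "height")])) == 0
  report <- reject(report, "vitals", "no_measurement", sum(empty))
  vit <- vit[!empty, , drop = FALSE]

  keep_cols <- list(
    patients = c("patient_id", "gp_id", "gender", "birth_year"),
    gps = c("gp_id", "gender", "birth_year", "urban_location"),
    encounters = c("patient_id", "date", "icpc2_code"),
    prescriptions = c("patient_id", "date", "atc_code", "end_date"),
    labs = c("patient_id", "date", "analyte", "value", "unit"),
    vitals = c("patient_id", "date", "systolic_bp", "diastolic_bp", "bmi",
               "weight", "height")
  )
  out <- emr_dataset(
    patients = pats[keep_cols$patients], gps = gps[keep_cols$gps],
    encounters = enc[keep_cols$encounters],
    prescriptions = rx[keep_cols$prescriptions],
    labs = labs[keep_cols$labs], vitals = vit[keep_cols$vitals],
    study_window = config$study_window
  )
  for (tab in emr_table_names()) {
    report[[tab]]$accepted <- report[[tab]]$rows_in - report[[tab]]$rejected
  }
  attr(out, "ingestion_report") <- report
  out
}

#' Retrieve the ingestion report of a dataset read from disk
#'
#' @param dataset An `emr_dataset` produced by [read_emr_tables()].
#' @return Per-table list with `rows_in`, `accepted`, `rejected` and a named
#'   list of rejection reasons, or `NULL` when the dataset was built in
#'   memory.
#' @export
ingestion_report <- function(dataset) attr(dataset, "ingestion_report")

#' Age in whole years at a date
#'
#' Ages are resolved at year precision (the data model carries birth year
#' only): `year(date) - birth_year`. Missing birth years propagate as `NA`.
#'
#' @param birth_year Integer vector of birth years (may contain `NA`).
#' @param date A `Date` (scalar or vector recycled against `birth_year`).
#' @return Integer ages.
#' @export
age_at <- function(birth_year, date) {
  as.integer(as.integer(format(as_date_safe(date), "%Y")) - birth_year)
}

#' Write a result table as delimited text
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (is.null(rows)) abort_ckdqi("rows must be non-null")
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_ckdqi("directory does not exist: %s", dir)
  if (format == "csv") readr::write_csv(rows, path, progress = FALSE)
  else readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Write an EMR dataset as the six standard delimited tables
#'
#' @param dataset An `emr_dataset`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"tsv"`.
#' @return Named vector of file paths, invisibly.
#' @export
write_emr_tables <- function(dataset, dir, format = c("csv", "tsv")) {
  format <- match.arg(format)
  validate_emr_dataset(dataset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- format
  paths <- setNames(file.path(dir, paste0(emr_table_names(), ".", ext)),
                    emr_table_names())
  for (tab in emr_table_names()) write_table(dataset[[tab]], paths[[tab]], format)
  invisible(paths)
}

#' @export
print.emr_dataset <- function(x, ...) {
  cat("<emr_dataset> study window", format(x$study_window[1]), "to",
      format(x$study_window[2]), "\n")
  for (tab in emr_table_names()) {
    cat(sprintf("  %-13s %8d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}
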