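latest_value_per_patient <- function(tab) {
  tab |>
    dplyr::arrange(.data$patient_id, .data$date) |>
    dplyr::slice_tail(n = 1, by = "patient_id")
}

summarise_continuous <- function(x, n_total, characteristic, unit = "") {
  x <- x[!is.na(x)]
  tibble::tibble(
    characteristic = characteristic, level = unit,
    n = length(x), pct = 100 * length(x) / n_total,
    median = if (length(x)) median(x) else NA_real_,
    iqr_low = if (length(x)) unname(quantile(x, 0.25)) else NA_real_,
    iqr_high = if (length(x)) unname(quantile(x, 0.75)) else NA_real_
  )
}

summarise_categorical <- function(x, characteristic) {
  known <- !is.na(x)
  n_known <- sum(known)
  lv <- if (is.factor(x)) levels(x) else sort(unique(x[known]))
  rows <- lapply(lv, function(l) {
    tibble::tibble(characteristic = characteristic, level = as.character(l),
                   n = sum(x[known] == l),
                   pct = if (n_known) 100 * sum(x[known] == l) / n_known
                         else NA_real_,
                   median = NA_real_, iqr_low = NA_real_, iqr_high = NA_real_)
  })
  missing_row <- tibble::tibble(
    characteristic = characteristic, level = "missing", n = sum(!known),
    pct = 100 * sum(!known) / length(x),
    median = NA_real_, iqr_low = NA_real_, iqr_high = NA_real_)
  dplyr::bind_rows(c(rows, list(missing_row)))
}

#' Descriptive characteristics of a cohort
#'
#' Counts and percentages for categorical characteristics (percentage
#' denominators use pairwise deletion: the non-missing count per
#' characteristic, with missingness reported separately) and median (IQR)
#' for continuous ones, including the latest laboratory and vital values
#' per patient during the study period.
#'
#' @param cohort A cohort tibble ([build_rf_cohort()] or
#'   [build_ckd_cohort()]).
#' @param dataset The `emr_dataset`.
#' @param age_breaks Left-closed cut points for age-at-index categories.
#' @return Tibble `characteristic`, `level`, `n`, `pct`, `median`,
#'   `iqr_low`, `iqr_high`.
#' @export
describe_cohort <- function(cohort, dataset, age_breaks = c(65, 80)) {
  pat <- dataset$patients[dataset$patients$patient_id %in% cohort$patient_id, ]
  m <- match(cohort$patient_id, pat$patient_id)
  age <- age_at(pat$birth_year[m], cohort$index_date)
  n_total <- nrow(cohort)
  out <- list(
    tibble::tibble(characteristic = "n_patients", level = "", n = n_total,
                   pct = NA_real_, median = NA_real_, iqr_low = NA_real_,
                   iqr_high = NA_real_),
    summarise_categorical(pat$gender[m], "gender"),
    summarise_continuous(age, n_total, "age_at_inclusion", "years"),
    summarise_categorical(cut(age, c(-Inf, age_breaks, Inf), right = FALSE),
                          "age_category")
  )
  for (cond in intersect(c("has_diabetes", "has_hypertension", "has_ecvd"),
                         names(cohort))) {
    out <- c(out, list(summarise_categorical(cohort[[cond]], cond)))
  }
  if ("g_stage" %in% names(cohort)) {
    out <- c(out, list(summarise_categorical(cohort$g_stage, "g_stage"),
                       summarise_categorical(cohort$a_stage, "a_stage")))
  }
  labs <- dataset$labs[dataset$labs$patient_id %in% cohort$patient_id, ]
  for (an in intersect(names(analyte_units()), unique(labs$analyte))) {
    latest <- latest_value_per_patient(labs[labs$analyte == an, ])
    vals <- latest$value[match(cohort$patient_id, latest$patient_id)]
    out <- c(out, list(summarise_continuous(
      vals, n_total, paste0("latest_", an), unname(analyte_units()[an]))))
  }
  vit <- dataset$vitals[dataset$vitals$patient_id %in% cohort$patient_id, ]
  if (nrow(vit)) {
    for (col in c("systolic_bp", "diastolic_bp")) {
      sub <- vit[!is.na(vit[[col]]), c("patient_id", "date", col)]
      if (!nrow(sub)) next
      latest <- latest_value_per_patient(sub)
      vals <- latest[[col]][match(cohort$patient_id, latest$patient_id)]
      out <- c(out, list(summarise_continuous(vals, n_total,
                                              paste0("latest_", col),
                                              "mmHg")))
    }
    bmi <- bmi_events(dataset)
    bmi <- bmi[bmi$patient_id %in% cohort$patient_id, ]
    if (nrow(bmi)) {
      latest <- latest_value_per_patient(bmi)
      vals <- latest$bmi[match(cohort$patient_id, latest$patient_id)]
      out <- c(out, list(summarise_continuous(vals, n_total, "latest_bmi",
                                              "kg/m2")))
    }
  }
  dplyr::bind_rows(out)
}

#' Pipeline run configuration
#'
#' @param tables Named list of input table paths (see [read_emr_tables()]),
#'   or `NULL` to simulate.
#' @param synth A [simulation_config()] used when `tables` is `NULL`.
#' @param rules Condition rule config passed to [load_rule_set()].
#' @param qi A [qi_config()].
#' @param detection A [ckd_detection_config()].
#' @param ingestion An [ingestion_config()].
#' @param fit_models Fit the variation models (full + null) per indicator.
#' @param nagq Quadrature nodes for model fitting.
#' @param min_denominator Smallest denominator for which models are fitted.
#' @param out_dir Output directory.
#' @param seed Integer seed (overrides the synth config's seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(tables = NULL, synth = simulation_config(),
                       rules = NULL, qi = qi_config(),
                       detection = ckd_detection_config(),
                       ingestion = ingestion_config(),
                       fit_models = TRUE, nagq = 1L, min_denominator = 50L,
                       out_dir = tempfile("ckdqi_run_"), seed = 1L) {
  if (!is.null(tables) && !is.null(synth)) {
    # real tables win; synth config is ignored when tables are supplied
    synth <- NULL
  }
  if (is.null(tables) && is.null(synth)) {
    abort_ckdqi("supply exactly one of `tables` or `synth`")
  }
  structure(list(tables = tables, synth = synth, rules = rules, qi = qi,
                 detection = detection, ingestion = ingestion,
                 fit_models = fit_models, nagq = nagq,
                 min_denominator = min_denominator, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

fit_variation_safe <- function(qi_result, covariates, nagq) {
  tryCatch(analyse_qi_variation(qi_result, covariates, nagq = nagq),
           ckdqi_error = function(e) NULL, error = function(e) NULL)
}

#' Run the full quality-of-care pipeline
#'
#' Reads (or simulates) the EMR tables, detects laboratory-defined CKD,
#' labels predisposing conditions, builds the renal-function assessment and
#' CKD care cohorts, evaluates the fourteen quality indicators, fits the
#' variation models, and writes the result bundle: cohort characteristics
#' and membership tables, the indicator summary, per-indicator forest and
#' model files, per-patient achievement flags, and a run manifest. Given
#' the same configuration and seed, reruns are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the dataset, cohorts, QI results,
#'   variation summaries and output paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_ckdqi("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  truth <- NULL
  if (!is.null(config$tables)) {
    dataset <- stage("ingest", read_emr_tables(config$tables,
                                               config$ingestion))
  } else {
    synth <- config$synth
    synth$seed <- config$seed
    gen <- stage("simulate", generate_emr(synth))
    dataset <- gen$dataset
    truth <- gen$truth
  }

  rules <- stage("rules", load_rule_set(config$rules))
  evidence <- stage("ckd_detection", detect_ckd_all(dataset,
                                                    config$detection))
  timelines <- stage("condition_labelling", label_conditions(dataset, rules))
  baseline <- stage("baseline", build_baseline(dataset))
  rf_cohort <- stage("rf_cohort",
                     build_rf_cohort(dataset, baseline, timelines))
  ckd_cohort <- stage("ckd_cohort",
                      build_ckd_cohort(dataset, baseline, evidence,
                                       timelines))
  cohorts <- list(rf = rf_cohort, ckd = ckd_cohort)
  qi <- stage("qi_engine", evaluate_all(cohorts, dataset, config$qi))

  cov_rf <- stage("covariates",
                  build_covariate_table(dataset, rf_cohort,
                                        patient_age_breaks = c(40, 60, 80)))
  cov_ckd <- stage("covariates",
                   build_covariate_table(dataset, ckd_cohort,
                                         patient_age_breaks = c(65, 80)))
  variation <- list()
  if (config$fit_models) {
    for (i in 1:14) {
      r <- qi$results[[i]]
      if (r$n_denominator < config$min_denominator) next
      covs <- if (i <= 3) cov_rf else cov_ckd
      v <- fit_variation_safe(r, covs, config$nagq)
      if (!is.null(v)) variation[[paste0("qi", i)]] <- v
    }
  }

  # --- outputs ---
  paths <- list()
  w <- function(name, rows) {
    p <- file.path(out_dir, name)
    write_table(rows, p)
    paths[[name]] <<- p
  }
  rf_out <- rf_cohort
  rf_out$followup_months <- round(rf_out$followup_months, 2)
  ckd_out <- ckd_cohort
  ckd_out$followup_months <- round(ckd_out$followup_months, 2)
  w("rf_cohort.csv", rf_out)
  w("ckd_cohort.csv", ckd_out)
  desc <- dplyr::bind_rows(
    dplyr::mutate(describe_cohort(rf_cohort, dataset,
                                  age_breaks = c(40, 60, 80)),
                  cohort = "rf_assessment", .before = 1),
    dplyr::mutate(describe_cohort(ckd_cohort, dataset,
                                  age_breaks = c(65, 80)),
                  cohort = "ckd_care", .before = 1)
  )
  desc$pct <- round(desc$pct, 1)
  for (cc in c("median", "iqr_low", "iqr_high")) desc[[cc]] <- round(desc[[cc]], 2)
  w("cohort_characteristics.csv", desc)

  summ <- qi$summary
  summ$achievement_rate <- round(summ$achievement_rate, 1)
  summ$ror <- round(vapply(paste0("qi", summ$qi_id), function(k) {
    if (!is.null(variation[[k]])) variation[[k]]$ror else NA_real_
  }, numeric(1)), 1)
  summ$icc <- round(vapply(paste0("qi", summ$qi_id), function(k) {
    if (!is.null(variation[[k]])) variation[[k]]$icc else NA_real_
  }, numeric(1)), 2)
  w("qi_summary.csv", summ)

  flags <- dplyr::bind_rows(lapply(qi$results, function(r) {
    dplyr::mutate(r$flags, qi_id = r$qi_id, .before = 1)
  }))
  w("qi_flags.csv", flags)

  for (k in names(variation)) {
    v <- variation[[k]]
    forest <- v$or_table
    forest[c("or", "ci_low", "ci_high")] <-
      lapply(forest[c("or", "ci_low", "ci_high")], round, digits = 4)
    w(sprintf("forest_%s.csv", k), forest)
    model_json <- list(
      qi_id = v$qi_id,
      achievement_rate = v$achievement_rate,
      full = list(beta = as.list(v$full_model$beta),
                  se = as.list(sqrt(diag(v$full_model$beta_cov))),
                  sigma2_b = v$full_model$sigma2_b,
                  loglik = v$full_model$loglik,
                  n_obs = v$full_model$n_obs,
                  n_clusters = v$full_model$n_clusters),
      null = list(sigma2_b = v$sigma2_b_null, icc = v$icc, ror = v$ror,
                  loglik = v$null_model$loglik,
                  n_obs = v$null_model$n_obs,
                  n_clusters = v$null_model$n_clusters)
    )
    p <- file.path(out_dir, sprintf("model_%s.json", k))
    jsonlite::write_json(model_json, p, auto_unbox = TRUE, digits = 10)
    paths[[basename(p)]] <- p
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ckdqi")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    input = if (is.null(config$tables)) "synthetic" else "tables",
    row_counts = lapply(dataset[emr_table_names()], nrow),
    n_baseline = length(baseline),
    n_rf_cohort = nrow(rf_cohort),
    n_ckd_cohort = nrow(ckd_cohort),
    models_fitted = names(variation)
  )
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = 10)
  paths[["manifest.json"]] <- p

  invisible(list(dataset = dataset, truth = truth, evidence = evidence,
                 timelines = timelines, baseline = baseline,
                 cohorts = cohorts, qi = qi, variation = variation,
                 summary = summ, paths = paths, manifest = manifest))
}

#' Read a cohort membership export back in
#'
#' Parses a cohort CSV written by [run_pipeline()] (the package's analogue
#' of a deposited analysis-cohort dataset), restoring dates and stage
#' factors.
#'
#' @param path CSV path.
#' @return Cohort tibble.
#' @export
read_cohort_export <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("index_date", "last_contact", "index_diabetes",
                          "index_hypertension", "index_ecvd"), names(d))) {
    d[[col]] <- as_date_safe(d[[col]])
  }
  if ("g_stage" %in% names(d)) {
    d$g_stage <- factor(d$g_stage, levels = c("G1", "G2", "G3a", "G3b",
                                              "G4", "G5"))
  }
  if ("a_stage" %in% names(d)) {
    d$a_stage <- factor(d$a_stage, levels = c("A1", "A2", "A3"))
  }
  d
}
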