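# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# invert the CKD-EPI creatinine equation: serum creatinine (umol/l) that
# yields a given eGFR for age/sex (female/male)
inverse_ckd_epi <- function(egfr, age, sex) {
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  a <- 141 * 0.993^age * ifelse(female, 1.018, 1)
  r <- egfr / a
  scr_mgdl <- ifelse(r < 1, kappa * r^(-1 / 1.209), kappa * r^(1 / alpha))
  scr_mgdl * 88.42
}

#' Simulation configuration for the synthetic EMR generator
#'
#' Defines the "swiss-gp" generative scenario: patients clustered within
#' GPs, one independent GP-level random intercept per care behaviour
#' (renal-function testing, albuminuria testing, RAAS/statin/NSAID
#' prescribing), per-visit care events drawn from logistic models, and
#' longitudinal renal labs from a latent linearly declining eGFR
#' trajectory. Default intercept SDs are chosen so that the latent-scale
#' ICCs of the simulated behaviours span the range typically reported for
#' primary-care process indicators (about 0.05-0.3).
#'
#' @param n_gps Number of GPs.
#' @param patients_per_gp Mean patients per GP (negative-binomial).
#' @param patients_dispersion Negative-binomial size parameter.
#' @param sigma_b Named list of GP intercept SDs (log-odds scale) for
#'   `rf_testing`, `albuminuria_testing`, `raas`, `statin`, `nsaid`.
#' @param baseline_logit Named list of baseline log-odds for the same
#'   behaviours: per-visit ordering propensity for `rf_testing`,
#'   `albuminuria_testing` and `nsaid`; per-patient treatment propensity
#'   for the persistent `raas` and `statin` therapies.
#' @param fixed_effect_log_odds Named list of covariate effects (log-odds)
#'   added to the testing propensities: `male`, `diabetes`, `hypertension`,
#'   `ecvd`.
#' @param prevalence Named list of condition prevalences (`diabetes`,
#'   `hypertension`, `ecvd`).
#' @param visits_per_year Poisson visit rate per patient-year.
#' @param egfr_intercept,egfr_age_slope,egfr_sd Latent eGFR at age 20
#'   (mL/min/1.73 m^2), decrease per year of age, and between-patient SD.
#' @param egfr_annual_decline Latent eGFR decline per follow-up year.
#' @param creatinine_cv Lognormal measurement noise SD on serum creatinine.
#' @param study_window Length-2 Date vector.
#' @param seed Integer seed; the generator is deterministic given
#'   (config, seed).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_gps = 100,
                              patients_per_gp = 60,
                              patients_dispersion = 8,
                              sigma_b = list(rf_testing = 1.2,
                                             albuminuria_testing = 1.1,
                                             raas = 0.5, statin = 0.5,
                                             nsaid = 0.5),
                              baseline_logit = list(rf_testing = -1.75,
                                                    albuminuria_testing = -3.7,
                                                    raas = -1.6, statin = 0.1,
                                                    nsaid = -3.2),
                              fixed_effect_log_odds = list(male = 0.2,
                                                           diabetes = 0.4,
                                                           hypertension = 0.1,
                                                           ecvd = 0.2),
                              prevalence = list(diabetes = 0.10,
                                                hypertension = 0.30,
                                                ecvd = 0.10),
                              visits_per_year = 4,
                              egfr_intercept = 100, egfr_age_slope = 0.9,
                              egfr_sd = 15, egfr_annual_decline = 1.2,
                              creatinine_cv = 0.06,
                              study_window = as.Date(c("2013-01-01",
                                                       "2019-12-31")),
                              seed = 1L) {
  stopifnot(n_gps >= 2, patients_per_gp > 0,
            all(unlist(sigma_b) >= 0),
            all(unlist(prevalence) >= 0 & unlist(prevalence) <= 1),
            visits_per_year > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Load a simulation configuration from a YAML scenario file
#'
#' The package ships its default scenario as
#' `system.file("extdata", "swiss_gp.yaml", package = "ckdqi")`.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [simulation_config()].
#' @return A `simulation_config`.
#' @export
simulation_config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$study_window)) {
    args$study_window <- as.Date(unlist(args$study_window))
  }
  do.call(simulation_config, args)
}

#' Generate a synthetic EMR dataset with known ground truth
#'
#' Draws a fully linked [emr_dataset()] under a [simulation_config()]:
#' GPs with demographics and per-behaviour random intercepts, patients
#' clustered within GPs, a homogeneous-Poisson visit process, condition
#' onsets emitting ICPC-2 codes, prescriptions and diagnostic labs, and
#' serum creatinine / eGFR / ACR / UAC trajectories with measurement noise.
#' Deterministic given `(config, config$seed)`.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (an `emr_dataset`) and `truth` (class
#'   `synthetic_truth`: the config, realised per-GP intercepts, and per
#'   behaviour the theoretical latent-scale ICC and large-sample range odds
#'   ratio `exp(3.2897 * sigma_b)`).
#' @export
generate_emr <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, generate_emr_impl(config))
}

generate_emr_impl <- function(cfg) {
  win <- as_date_safe(cfg$study_window)
  win_days <- as.numeric(win[2] - win[1])
  behaviours <- c("rf_testing", "albuminuria_testing", "raas", "statin",
                  "nsaid")

  # GPs ----
  n_gps <- cfg$n_gps
  gp_id <- sprintf("gp%03d", seq_len(n_gps))
  gp_gender <- sample(c("female", "male", "unknown"), n_gps, replace = TRUE,
                      prob = c(0.435, 0.55, 0.015))
  gp_birth <- as.integer(format(win[1], "%Y")) - round(rnorm(n_gps, 49, 9))
  gp_birth[runif(n_gps) < 0.05] <- NA_integer_
  gps <- tibble::tibble(
    gp_id = gp_id, gender = gp_gender, birth_year = gp_birth,
    urban_location = runif(n_gps) < 0.75
  )
  b <- sapply(behaviours, function(bh) {
    rnorm(n_gps, 0, cfg$sigma_b[[bh]] %||% 0)
  })
  rownames(b) <- gp_id

  # Patients ----
  n_per_gp <- pmax(1L, stats::rnbinom(n_gps, mu = cfg$patients_per_gp,
                                      size = cfg$patients_dispersion))
  n_pat <- sum(n_per_gp)
  p_gp <- rep(gp_id, n_per_gp)
  patient_id <- sprintf("p%06d", seq_len(n_pat))
  gender <- sample(c("female", "male", "other"), n_pat, replace = TRUE,
                   prob = c(0.525, 0.470, 0.005))
  age_entry <- pmin(92, pmax(18, 18 + 77 * stats::rbeta(n_pat, 1.6, 1.9)))
  entry_offset <- floor(runif(n_pat, 0, 365))
  entry <- win[1] %d+% entry_offset
  birth_year <- as.integer(format(entry, "%Y")) - round(age_entry)
  patients <- tibble::tibble(patient_id = patient_id, gp_id = p_gp,
                             gender = gender, birth_year = birth_year)

  prev <- cfg$prevalence
  dm <- runif(n_pat) < prev$diabetes
  hyp <- runif(n_pat) < prev$hypertension
  cvd <- runif(n_pat) < prev$ecvd
  onset <- function(has) {
    o <- entry %d+% round(runif(n_pat, -3 * 365, 2 * 365))
    o <- pmax(o, win[1])
    o[!has] <- NA
    o
  }
  dm_onset <- onset(dm); hyp_onset <- onset(hyp); cvd_onset <- onset(cvd)

  egfr0 <- pmax(8, cfg$egfr_intercept - cfg$egfr_age_slope * (age_entry - 20) +
                  rnorm(n_pat, 0, cfg$egfr_sd))
  log_acr_true <- rnorm(n_pat, log(0.8) + 1.1 * dm + 0.5 * hyp +
                          0.012 * pmax(0, 60 - egfr0) * 2, 1.0)
  bmi_true <- pmax(16, rnorm(n_pat, 27, 4.5))
  height <- round(rnorm(n_pat, ifelse(gender == "male", 176, 164), 7))

  # Visit process ----
  span_days <- as.numeric(win[2] - entry)
  n_visits <- pmax(1L, rpois(n_pat, cfg$visits_per_year * span_days / 365.25))
  vi <- rep(seq_len(n_pat), n_visits)         # visit -> patient index
  v_date <- entry[vi] %d+% floor(runif(length(vi)) * (span_days[vi] + 1))
  ord <- order(vi, v_date)
  vi <- vi[ord]; v_date <- v_date[ord]
  n_v <- length(vi)
  v_gp <- match(p_gp[vi], gp_id)
  years_in <- as.numeric(v_date - entry[vi]) / 365.25
  v_age <- age_at(birth_year[vi], v_date)

  eff <- cfg$fixed_effect_log_odds
  x_eff <- eff$male * (gender[vi] == "male") + eff$diabetes * dm[vi] +
    eff$hypertension * hyp[vi] + eff$ecvd * cvd[vi]
  lo <- cfg$baseline_logit

  # Encounters (every visit; condition codes on/after onset) ----
  icpc <- rep(NA_character_, n_v)
  code_after <- function(onset_dates, codes, p_later = 0.10) {
    act <- !is.na(onset_dates[vi]) & v_date >= onset_dates[vi]
    # the first visit at/after onset always carries a code; later active
    # visits repeat it occasionally
    idx_first <- unlist(tapply(seq_len(n_v)[act], vi[act],
                               function(ix) ix[1]))
    sel <- rep(FALSE, n_v)
    sel[idx_first] <- TRUE
    sel <- sel | (act & runif(n_v) < p_later)
    list(sel = sel, code = sample(codes, n_v, replace = TRUE))
  }
  dmx <- code_after(dm_onset, c("T90", "T89"))
  hyx <- code_after(hyp_onset, c("K86", "K87"))
  cvx <- code_after(cvd_onset, c("K74", "K75", "K76", "K90", "K92"))
  icpc[cvx$sel] <- cvx$code[cvx$sel]
  icpc[hyx$sel] <- hyx$code[hyx$sel]
  icpc[dmx$sel] <- dmx$code[dmx$sel]
  encounters <- tibble::tibble(patient_id = patient_id[vi], date = v_date,
                               icpc2_code = icpc)

  # Renal labs ----
  egfr_true <- pmax(4, egfr0[vi] -
                      (cfg$egfr_annual_decline +
                         0.8 * (dm[vi] | hyp[vi])) * years_in)
  p_rf <- plogis(lo$rf_testing + b[cbind(v_gp, 1)] + x_eff)
  rf_test <- runif(n_v) < p_rf
  derivable <- gender[vi] %in% c("female", "male") & !is.na(v_age) & v_age >= 18
  scr_rows <- rf_test & derivable
  scr_val <- inverse_ckd_epi(egfr_true[scr_rows], v_age[scr_rows],
                             gender[vi][scr_rows]) *
    exp(rnorm(sum(scr_rows), 0, cfg$creatinine_cv))
  # labs report eGFR alongside creatinine for a subset; patients whose
  # creatinine cannot back an eGFR (gender "other") get a reported eGFR
  egfr_rep <- rf_test & (!derivable | runif(n_v) < 0.25)
  egfr_rep_val <- pmax(2, egfr_true[egfr_rep] *
                         exp(rnorm(sum(egfr_rep), 0, cfg$creatinine_cv)))

  p_alb <- plogis(lo$albuminuria_testing + b[cbind(v_gp, 2)] + x_eff)
  alb_test <- runif(n_v) < p_alb
  alb_as_acr <- runif(n_v) < 0.5
  acr_rows <- alb_test & alb_as_acr
  uac_rows <- alb_test & !alb_as_acr
  acr_val <- exp(log_acr_true[vi][acr_rows] + rnorm(sum(acr_rows), 0, 0.25))
  uac_val <- exp(log_acr_true[vi][uac_rows] + log(8) +
                   rnorm(sum(uac_rows), 0, 0.35))

  other_lab <- function(rows, analyte, mean, sd, lower) {
    tibble::tibble(patient_id = patient_id[vi][rows], date = v_date[rows],
                   analyte = analyte,
                   value = pmax(lower, rnorm(sum(rows), mean, sd)),
                   unit = unname(analyte_units()[analyte]))
  }
  cbc_rows <- runif(n_v) < 0.25
  na_rows <- runif(n_v) < 0.30
  k_rows <- runif(n_v) < 0.30
  urea_rows <- runif(n_v) < 0.15
  alp_rows <- runif(n_v) < 0.08
  ca_rows <- runif(n_v) < 0.08
  ph_rows <- runif(n_v) < 0.08
  pth_rows <- runif(n_v) < 0.03
  hba_rows <- runif(n_v) < ifelse(dm[vi], 0.30, 0.05)
  hba_val <- pmax(4, rnorm(n_v, ifelse(dm[vi], 7.2, 5.6),
                           ifelse(dm[vi], 1.2, 0.4)))

  labs <- dplyr::bind_rows(
    tibble::tibble(patient_id = patient_id[vi][scr_rows],
                   date = v_date[scr_rows], analyte = "serum_creatinine",
                   value = scr_val, unit = "umol/l"),
    tibble::tibble(patient_id = patient_id[vi][egfr_rep],
                   date = v_date[egfr_rep], analyte = "egfr",
                   value = egfr_rep_val, unit = "ml/min/1.73m2"),
    tibble::tibble(patient_id = patient_id[vi][acr_rows],
                   date = v_date[acr_rows], analyte = "acr",
                   value = acr_val, unit = "mg/mmol"),
    tibble::tibble(patient_id = patient_id[vi][uac_rows],
                   date = v_date[uac_rows], analyte = "uac",
                   value = uac_val, unit = "mg/l"),
    other_lab(cbc_rows, "hemoglobin", 133, 14, 60),
    other_lab(na_rows, "sodium", 141, 2.5, 120),
    other_lab(k_rows, "potassium", 4.3, 0.4, 2.5),
    other_lab(urea_rows, "urea", 8.5, 3, 1.5),
    other_lab(alp_rows, "alkaline_phosphatase", 80, 25, 20),
    other_lab(ca_rows, "calcium", 2.36, 0.12, 1.6),
    other_lab(ph_rows, "phosphate", 1.1, 0.18, 0.4),
    other_lab(pth_rows, "parathyroid_hormone", 65, 25, 8),
    tibble::tibble(patient_id = patient_id[vi][hba_rows],
                   date = v_date[hba_rows], analyte = "hba1c",
                   value = hba_val[hba_rows], unit = "%")
  )

  # Persistent treatment decisions: RAAS inhibitors and statins are
  # patient-level choices (the GP intercept acts on that choice) followed
  # by repeat scripts at visits; NSAIDs below remain episodic per-visit.
  gp_of_pat <- match(p_gp, gp_id)
  on_raas <- runif(n_pat) < plogis(lo$raas + 3.0 * (hyp | dm) +
                                     2.0 * (egfr0 < 60) +
                                     b[cbind(gp_of_pat, 3)])
  on_statin <- runif(n_pat) < plogis(lo$statin + 0.8 * (cvd | dm) +
                                       b[cbind(gp_of_pat, 4)])

  # Vitals: each patient has a persistent true blood-pressure level (lower
  # under antihypertensive treatment); visit readings scatter narrowly
  # around it, so chronic hypertension is a patient property rather than an
  # artefact of reading noise
  bp_rows <- runif(n_v) < 0.5
  p_sys <- rnorm(n_pat, 128 + 14 * hyp - 6 * on_raas, 10)
  p_dia <- rnorm(n_pat, 75 + 7 * hyp - 3 * on_raas, 7)
  sys <- round(rnorm(n_v, p_sys[vi], 7))
  dia <- round(rnorm(n_v, p_dia[vi], 5))
  bmi_rows <- runif(n_v) < 0.20
  as_wh <- runif(n_v) < 0.3   # report weight+height instead of BMI
  bmi_meas <- bmi_true[vi] + rnorm(n_v, 0, 0.7)
  vitals <- tibble::tibble(
    patient_id = patient_id[vi], date = v_date,
    systolic_bp = ifelse(bp_rows, pmax(70, sys), NA_real_),
    diastolic_bp = ifelse(bp_rows, pmax(40, dia), NA_real_),
    bmi = ifelse(bmi_rows & !as_wh, round(bmi_meas, 1), NA_real_),
    weight = ifelse(bmi_rows & as_wh,
                    round(bmi_meas * (height[vi] / 100)^2, 1), NA_real_),
    height = ifelse(bmi_rows & as_wh, height[vi], NA_real_)
  )
  vitals <- vitals[bp_rows | bmi_rows, ]

  # Prescriptions ----
  rx_block <- function(rows, codes) {
    end <- rep(as.Date(NA), sum(rows))
    has_end <- runif(sum(rows)) < 0.3
    end[has_end] <- v_date[rows][has_end] %d+% 90
    end <- pmin(end, win[2])
    tibble::tibble(patient_id = patient_id[vi][rows], date = v_date[rows],
                   atc_code = sample(codes, sum(rows), replace = TRUE),
                   end_date = end)
  }
  raas_rows <- on_raas[vi] & runif(n_v) < 0.6
  statin_rows <- on_statin[vi] & !is.na(v_age) & v_age >= 45 & v_age <= 85 &
    runif(n_v) < 0.5
  nsaid_rows <- runif(n_v) < plogis(lo$nsaid + b[cbind(v_gp, 5)])
  antidm_rows <- dm[vi] & !is.na(dm_onset[vi]) & v_date >= dm_onset[vi] &
    runif(n_v) < 0.35
  othhyp_rows <- hyp[vi] & !is.na(hyp_onset[vi]) & v_date >= hyp_onset[vi] &
    runif(n_v) < 0.15
  asa_rows <- cvd[vi] & runif(n_v) < 0.10
  prescriptions <- dplyr::bind_rows(
    rx_block(raas_rows, c("C09AA02", "C09AA05", "C09CA01", "C09CA06")),
    rx_block(statin_rows, c("C10AA01", "C10AA05", "C10AA07", "C10BA02")),
    rx_block(nsaid_rows, c("M01AB05", "M01AE01", "M01AH01")),
    rx_block(antidm_rows, c("A10BA02", "A10BB09", "A10AB05")),
    rx_block(othhyp_rows, c("C03AA03", "C07AB02", "C08CA01")),
    rx_block(asa_rows, c("B01AC06"))
  )

  dataset <- emr_dataset(
    patients = patients, gps = gps,
    encounters = dplyr::arrange(encounters, .data$patient_id, .data$date),
    prescriptions = dplyr::arrange(prescriptions, .data$patient_id,
                                   .data$date),
    labs = dplyr::arrange(labs, .data$patient_id, .data$date,
                          .data$analyte),
    vitals = dplyr::arrange(vitals, .data$patient_id, .data$date),
    study_window = win
  )
  truth <- structure(list(
    config = cfg,
    gp_intercepts = tibble::as_tibble(cbind(tibble::tibble(gp_id = gp_id),
                                            as.data.frame(b))),
    theoretical = tibble::tibble(
      behaviour = behaviours,
      sigma_b = unlist(cfg$sigma_b[behaviours], use.names = FALSE),
      icc = icc_latent(unlist(cfg$sigma_b[behaviours],
                              use.names = FALSE)^2),
      ror_large_sample = exp(2 * qnorm(0.95) *
                               unlist(cfg$sigma_b[behaviours],
                                      use.names = FALSE))
    )
  ), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate clustered binary outcomes with known truth
#'
#' Direct test harness for the variation models:
#' \eqn{y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(x'\beta + b_g))} with
#' \eqn{b_g \sim N(0, \sigma_b^2)}. The first element of `beta` is the
#' intercept; any further named elements become Bernoulli(0.5) binary
#' covariates with the given log-odds effects.
#'
#' @param n_clusters,n_per_cluster Design size.
#' @param sigma_b Random-intercept SD.
#' @param beta Named numeric vector; first element is the intercept.
#' @param seed Integer seed.
#' @return List with `data` (tibble `y`, `gp_id`, covariates) and `truth`
#'   (`sigma_b`, `beta`, realised `intercepts`).
#' @export
generate_clustered_binary <- function(n_clusters, n_per_cluster, sigma_b,
                                      beta = c(intercept = -0.5), seed = 1L) {
  stopifnot(n_clusters >= 2, n_per_cluster >= 1, sigma_b >= 0)
  with_local_seed(seed, {
    g <- rep(sprintf("c%04d", seq_len(n_clusters)), each = n_per_cluster)
    bg <- rnorm(n_clusters, 0, sigma_b)
    eta <- beta[[1]] + rep(bg, each = n_per_cluster)
    n <- length(g)
    dat <- tibble::tibble(gp_id = g)
    if (length(beta) > 1) {
      for (j in 2:length(beta)) {
        x <- rbinom(n, 1, 0.5)
        dat[[names(beta)[j]]] <- x
        eta <- eta + beta[[j]] * x
      }
    }
    dat$y <- rbinom(n, 1, plogis(eta))
    list(data = dat,
         truth = list(sigma_b = sigma_b, beta = beta,
                      intercepts = setNames(bg, unique(g))))
  })
}
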