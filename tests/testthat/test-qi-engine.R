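# shared small simulated pipeline state for the QI tests
qi_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_emr(simulation_config(n_gps = 8, patients_per_gp = 30,
                                            seed = 303))
      ds <- gen$dataset
      ev <- detect_ckd_all(ds)
      tl <- label_conditions(ds)
      bl <- build_baseline(ds)
      cache <<- list(
        ds = ds,
        cohorts = list(rf = build_rf_cohort(ds, bl, tl),
                       ckd = build_ckd_cohort(ds, bl, ev, tl))
      )
    }
    cache
  }
})

test_that("withholding NSAIDs is achieved exactly when no NSAID starts in-window", {
  fx <- qi_fixture()
  r <- evaluate_qi(11, fx$cohorts, fx$ds)
  den <- r$flags[r$flags$in_denominator, ]
  rx <- fx$ds$prescriptions
  nsaid <- rx[startsWith(rx$atc_code, "M01A"), ]
  idx <- fx$cohorts$ckd$index_date[match(den$patient_id,
                                         fx$cohorts$ckd$patient_id)]
  for (i in seq_len(nrow(den))) {
    p <- nsaid[nsaid$patient_id == den$patient_id[i], ]
    started <- any(p$date > idx[i] & as.numeric(p$date - idx[i]) < 365)
    overlap <- any(!is.na(p$end_date) & p$date <= idx[i] &
                     p$end_date > idx[i])
    expect_equal(den$achieved[i], !(started || overlap))
  }
  # aspirin (B01AC06) never counts as an NSAID
  expect_false(any(startsWith(nsaid$atc_code, "B01")))
})

test_that("albuminuria monitoring counts only in-window assessments", {
  t <- tiny_emr_tables()
  # make p2 a confirmed G3a patient with long follow-up and one UAC
  t$labs <- rbind(t$labs, data.frame(
    patient_id = c("p2", "p2", "p2"),
    date = c("2014-05-01", "2014-09-01", "2015-03-01"),
    analyte = c("egfr", "egfr", "uac"),
    value = c("50", "48", "30"),
    unit = c("ml/min/1.73m2", "ml/min/1.73m2", "mg/l")))
  t$encounters <- rbind(t$encounters, data.frame(
    patient_id = "p2", date = "2017-01-01", icpc2_code = ""))
  ds <- read_emr_tables(write_tiny_emr(tables = t))
  ev <- detect_ckd_all(ds)
  tl <- label_conditions(ds)
  bl <- build_baseline(ds)
  cohorts <- list(rf = build_rf_cohort(ds, bl, tl),
                  ckd = build_ckd_cohort(ds, bl, ev, tl))
  # index 2014-09-01; UAC at +6 months is inside the 18-month window
  r <- evaluate_qi(5, cohorts, ds)
  expect_true(r$flags$achieved[r$flags$patient_id == "p2"])
  # push the UAC beyond 18 months -> not achieved
  t2 <- t
  t2$labs$date[t2$labs$analyte == "uac"] <- "2016-04-01"
  ds2 <- read_emr_tables(write_tiny_emr(tables = t2))
  cohorts2 <- list(rf = cohorts$rf,
                   ckd = build_ckd_cohort(ds2, build_baseline(ds2),
                                          detect_ckd_all(ds2),
                                          label_conditions(ds2)))
  r2 <- evaluate_qi(5, cohorts2, ds2)
  expect_false(r2$flags$achieved[r2$flags$patient_id == "p2"])
  # the single UAC of 30 mg/l also cannot itself confirm CKD
  expect_equal(ev$criterion[ev$patient_id == "p2"], "egfr")
})

test_that("blood-pressure target uses the latest complete reading", {
  t <- tiny_emr_tables()
  t$labs <- rbind(t$labs, data.frame(
    patient_id = c("p2", "p2"), date = c("2014-05-01", "2014-09-01"),
    analyte = "egfr", value = c("50", "48"), unit = "ml/min/1.73m2"))
  t$vitals <- rbind(t$vitals, data.frame(
    patient_id = c("p2", "p2"),
    date = c("2015-01-01", "2015-06-01"),
    systolic_bp = c("150", "135"), diastolic_bp = c("95", "85"),
    bmi = "", weight = "", height = ""))
  ds <- read_emr_tables(write_tiny_emr(tables = t))
  cohorts <- list(rf = NULL,
                  ckd = build_ckd_cohort(ds, build_baseline(ds),
                                         detect_ckd_all(ds),
                                         label_conditions(ds)))
  r <- evaluate_qi(12, cohorts, ds)
  p2 <- r$flags[r$flags$patient_id == "p2", ]
  expect_true(p2$in_denominator)
  expect_true(p2$achieved)   # latest reading 135/85 is below 140/90
})

test_that("numerators are subsets of denominators and rates are bounded", {
  fx <- qi_fixture()
  res <- evaluate_all(fx$cohorts, fx$ds)
  expect_equal(nrow(res$summary), 14)
  for (r in res$results) {
    f <- r$flags
    expect_true(all(!f$achieved[!f$in_denominator] %in% TRUE))
    expect_true(all(!is.na(f$achieved[f$in_denominator])))
    expect_equal(r$n_numerator, sum(f$achieved[f$in_denominator]))
    if (r$n_denominator > 0) {
      expect_gte(r$achievement_rate, 0)
      expect_lte(r$achievement_rate, 100)
      expect_equal(r$achievement_rate,
                   100 * r$n_numerator / r$n_denominator)
    }
  }
})

test_that("the diabetic BP-target denominator nests inside the general one", {
  fx <- qi_fixture()
  q12 <- evaluate_qi(12, fx$cohorts, fx$ds)
  q13 <- evaluate_qi(13, fx$cohorts, fx$ds)
  in12 <- q12$flags$patient_id[q12$flags$in_denominator]
  in13 <- q13$flags$patient_id[q13$flags$in_denominator]
  dm <- fx$cohorts$ckd$patient_id[fx$cohorts$ckd$has_diabetes]
  expect_true(all(in13 %in% intersect(in12, dm)))
})

test_that("achievement rates equal an independent per-patient recount", {
  fx <- qi_fixture()
  ckd <- fx$cohorts$ckd
  fu <- as.numeric(ckd$last_contact - ckd$index_date)
  g14 <- as.character(ckd$g_stage) %in% c("G1", "G2", "G3a", "G3b", "G4")
  members <- ckd[g14 & fu >= 548, ]
  want4 <- oracle_window_rate(members, fx$ds$labs,
                              c("serum_creatinine", "egfr"), 548)
  want5 <- oracle_window_rate(members, fx$ds$labs, c("acr", "uac"), 548)
  expect_equal(evaluate_qi(4, fx$cohorts, fx$ds)$achievement_rate, want4)
  expect_equal(evaluate_qi(5, fx$cohorts, fx$ds)$achievement_rate, want5)
  # assessment indicator recount on the per-condition index
  rf <- fx$cohorts$rf
  m1 <- rf[rf$eligible_diabetes, ]
  m1$index_date <- m1$index_diabetes
  want1 <- oracle_window_rate(m1, fx$ds$labs,
                              c("serum_creatinine", "egfr", "acr", "uac"), 548)
  expect_equal(evaluate_qi(1, fx$cohorts, fx$ds)$achievement_rate, want1)
})

test_that("extending follow-up never removes window-QI denominator membership", {
  fx <- qi_fixture()
  ds2 <- fx$ds
  # an extra late encounter for everyone extends every follow-up
  ds2$encounters <- dplyr::bind_rows(
    ds2$encounters,
    tibble::tibble(patient_id = ds2$patients$patient_id,
                   date = as.Date("2019-12-15"), icpc2_code = NA_character_))
  ev2 <- detect_ckd_all(ds2)
  tl2 <- label_conditions(ds2)
  bl2 <- build_baseline(ds2)
  cohorts2 <- list(rf = build_rf_cohort(ds2, bl2, tl2),
                   ckd = build_ckd_cohort(ds2, bl2, ev2, tl2))
  for (qi in c(1, 4, 9, 11)) {
    before <- evaluate_qi(qi, fx$cohorts, fx$ds)
    after <- evaluate_qi(qi, cohorts2, ds2)
    in_before <- before$flags$patient_id[before$flags$in_denominator]
    in_after <- after$flags$patient_id[after$flags$in_denominator]
    expect_true(all(in_before %in% in_after), info = paste("QI", qi))
  }
})

test_that("unknown indicator ids error", {
  fx <- qi_fixture()
  expect_error(evaluate_qi(15, fx$cohorts, fx$ds), "unknown qi_id")
  expect_error(evaluate_qi(0, fx$cohorts, fx$ds), "unknown qi_id")
})
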