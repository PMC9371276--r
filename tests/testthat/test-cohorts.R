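test_that("baseline requires a consultation and adulthood at first observation", {
  t <- tiny_emr_tables()
  # p4: aged 17 at first event -> excluded despite encounters
  t$patients <- rbind(t$patients, data.frame(
    patient_id = "p4", gp_id = "g1", gender = "male", birth_year = 1997L))
  t$encounters <- rbind(t$encounters, data.frame(
    patient_id = "p4", date = "2014-06-01", icpc2_code = ""))
  # p5: labs but no encounter -> excluded
  t$patients <- rbind(t$patients, data.frame(
    patient_id = "p5", gp_id = "g1", gender = "female", birth_year = 1960L))
  t$labs <- rbind(t$labs, data.frame(
    patient_id = "p5", date = "2014-06-01", analyte = "sodium",
    value = "141", unit = "mmol/l"))
  ds <- read_emr_tables(write_tiny_emr(tables = t))
  bl <- build_baseline(ds)
  expect_setequal(bl, c("p1", "p2", "p3"))
})

test_that("last contact is the maximum event date across all tables", {
  ds <- tiny_emr_dataset()
  expect_equal(last_contact(ds, "p1"), as.Date("2015-06-01"))
  expect_equal(last_contact(ds, "p3"), as.Date("2016-02-02"))
  # oracle: brute-force max over concatenated tables
  span <- observation_span(ds)
  for (id in span$patient_id) {
    all_dates <- c(ds$encounters$date[ds$encounters$patient_id == id],
                   ds$prescriptions$date[ds$prescriptions$patient_id == id],
                   ds$labs$date[ds$labs$patient_id == id],
                   ds$vitals$date[ds$vitals$patient_id == id])
    expect_equal(span$last_contact[span$patient_id == id], max(all_dates))
    expect_equal(span$first_observation[span$patient_id == id],
                 min(all_dates))
  }
})

test_that("RF cohort keeps per-condition eligibility with 18-month follow-up", {
  t <- tiny_emr_tables()
  # p1: diabetes evidence 2014-02-01, last contact 2015-06-01 (< 18 months)
  # -> not eligible; extend contact for eligibility in second pass
  ds <- read_emr_tables(write_tiny_emr(tables = t))
  tl <- label_conditions(ds)
  bl <- build_baseline(ds)
  rf <- build_rf_cohort(ds, bl, tl)
  expect_false("p1" %in% rf$patient_id)
  # p2: hypertension 2014-03-01, last contact 2014-09-01 -> also short
  t$encounters <- rbind(t$encounters, data.frame(
    patient_id = c("p1", "p2"), date = c("2016-05-05", "2017-01-01"),
    icpc2_code = c("", "")))
  ds2 <- read_emr_tables(write_tiny_emr(tables = t))
  tl2 <- label_conditions(ds2)
  rf2 <- build_rf_cohort(ds2, build_baseline(ds2), tl2)
  expect_setequal(rf2$patient_id, c("p1", "p2"))
  p1 <- rf2[rf2$patient_id == "p1", ]
  expect_true(p1$eligible_diabetes)
  expect_false(p1$eligible_hypertension)
  expect_equal(p1$index_date, as.Date("2014-02-01"))
  p2 <- rf2[rf2$patient_id == "p2", ]
  expect_true(p2$eligible_hypertension)
  expect_false(p2$eligible_diabetes)
})

test_that("a condition with short follow-up enters no assessment denominator", {
  # diabetes with 20 months of follow-up, eCVD with 10 months: the patient
  # is in the diabetes denominator only
  t <- tiny_emr_tables()
  t$encounters <- rbind(t$encounters, data.frame(
    patient_id = c("p1", "p1"), date = c("2015-04-01", "2015-10-01"),
    icpc2_code = c("K74", "")))
  ds <- read_emr_tables(write_tiny_emr(tables = t))
  tl <- label_conditions(ds)
  rf <- build_rf_cohort(ds, build_baseline(ds), tl)
  p1 <- rf[rf$patient_id == "p1", ]
  expect_equal(nrow(p1), 1)
  expect_true(p1$eligible_diabetes)      # 2014-02-01 .. 2015-10-01 = 20 mo
  expect_false(p1$eligible_ecvd)         # 2015-04-01 .. 2015-10-01 = 6 mo
  qi3 <- evaluate_qi(3, list(rf = rf, ckd = NULL), ds)
  expect_false(qi3$flags$in_denominator[qi3$flags$patient_id == "p1"])
  qi1 <- evaluate_qi(1, list(rf = rf, ckd = NULL), ds)
  expect_true(qi1$flags$in_denominator[qi1$flags$patient_id == "p1"])
})

test_that("CKD cohort excludes ever-G5 and unconfirmed patients", {
  t <- tiny_emr_tables()
  # p2 gets two low eGFRs > 90 days apart, p3 one low value only,
  # p1 confirmed but once staged G5
  t$labs <- rbind(t$labs, data.frame(
    patient_id = c("p2", "p2", "p3", "p1", "p1", "p1"),
    date = c("2014-05-01", "2014-09-01", "2015-01-01",
             "2015-01-01", "2015-05-01", "2016-01-01"),
    analyte = "egfr",
    value = c("50", "48", "44", "55", "52", "12"),
    unit = "ml/min/1.73m2"))
  ds <- read_emr_tables(write_tiny_emr(tables = t))
  ev <- detect_ckd_all(ds)
  tl <- label_conditions(ds)
  bl <- build_baseline(ds)
  ck <- build_ckd_cohort(ds, bl, ev, tl)
  expect_setequal(ck$patient_id, "p2")
  expect_equal(as.character(ck$g_stage), "G3a")
  expect_equal(ck$index_date, as.Date("2014-09-01"))
  expect_true(all(!ev$ever_g5[ev$patient_id == "p2"]))
  expect_true(ev$ever_g5[ev$patient_id == "p1"])
})

test_that("cohorts are subsets of baseline and may overlap", {
  gen <- generate_emr(simulation_config(n_gps = 6, patients_per_gp = 25,
                                        seed = 21))
  ds <- gen$dataset
  ev <- detect_ckd_all(ds)
  tl <- label_conditions(ds)
  bl <- build_baseline(ds)
  rf <- build_rf_cohort(ds, bl, tl)
  ck <- build_ckd_cohort(ds, bl, ev, tl)
  expect_true(all(rf$patient_id %in% bl))
  expect_true(all(ck$patient_id %in% bl))
  expect_gt(length(intersect(rf$patient_id, ck$patient_id)), 0)
  expect_true(all(ck$followup_months >= 0))
  # every CKD member is confirmed and never G5
  m <- ev[match(ck$patient_id, ev$patient_id), ]
  expect_true(all(m$ckd_confirmed))
  expect_true(all(!m$ever_g5))
})
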