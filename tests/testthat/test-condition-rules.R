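# brute-force oracle: scan every event of one patient against a rule set
oracle_first_condition <- function(rules, cond, enc, rx, labs, vitals) {
  r <- rules[[cond]]
  cand <- as.Date(character())
  for (i in seq_len(nrow(enc))) {
    for (p in r$icpc2_codes) {
      if (!is.na(enc$icpc2_code[i]) && startsWith(enc$icpc2_code[i], p)) {
        cand <- c(cand, enc$date[i])
      }
    }
  }
  for (i in seq_len(nrow(rx))) {
    for (p in r$atc_codes) {
      if (startsWith(rx$atc_code[i], p)) cand <- c(cand, rx$date[i])
    }
  }
  for (cr in r$lab_criteria) {
    for (i in seq_len(nrow(labs))) {
      if (labs$analyte[i] == cr$analyte &&
          do.call(cr$comparator, list(labs$value[i], cr$threshold))) {
        cand <- c(cand, labs$date[i])
      }
    }
  }
  for (cr in r$vital_criteria) {
    hits <- as.Date(character())
    for (i in seq_len(nrow(vitals))) {
      ok <- FALSE
      for (f in names(cr$fields)) {
        v <- vitals[[f]][i]
        if (!is.na(v) && do.call(cr$comparator, list(v, cr$fields[[f]]))) {
          ok <- TRUE
        }
      }
      if (ok) hits <- c(hits, vitals$date[i])
    }
    hits <- sort(hits)
    if (length(hits) >= cr$min_occurrences) {
      cand <- c(cand, hits[cr$min_occurrences])
    }
  }
  if (length(cand)) min(cand) else as.Date(NA)
}

test_that("defaults load, overrides merge, invalid configs error", {
  rules <- load_rule_set()
  expect_setequal(names(rules), c("diabetes", "hypertension", "ecvd"))
  over <- load_rule_set(list(diabetes = list(atc_codes = "A10A")))
  expect_equal(over$diabetes$atc_codes, "A10A")
  expect_equal(over$diabetes$icpc2_codes, rules$diabetes$icpc2_codes)
  expect_error(load_rule_set(list(gout = list())), "unknown condition")
  expect_error(load_rule_set(list(diabetes = list(
    lab_criteria = list(list(analyte = "hba1c", comparator = ">=",
                             threshold = -1))))), "positive")
})

test_that("rule sets round-trip through YAML", {
  path <- file.path(withr::local_tempdir(), "rules.yaml")
  yaml::write_yaml(list(diabetes = list(atc_codes = list("A10A", "A10B"))),
                   path)
  rules <- load_rule_set(path)
  expect_equal(unlist(rules$diabetes$atc_codes), c("A10A", "A10B"))
})

test_that("first evidence is the earliest firing criterion across sources", {
  t <- tiny_emr_tables()
  # p1: encounter T90 on 2015-03-01 would fire, but the A10 prescription on
  # 2014-02-01 is earlier -> first_diabetes = prescription date
  t$encounters <- rbind(t$encounters, data.frame(
    patient_id = "p1", date = "2015-03-01", icpc2_code = "T90"))
  ds <- read_emr_tables(write_tiny_emr(tables = t))
  tl <- label_conditions(ds, load_rule_set())
  expect_equal(tl$first_diabetes[tl$patient_id == "p1"],
               as.Date("2014-02-01"))
  # p2: K86 encounter and C09 prescription both on 2014-03-01
  expect_equal(tl$first_hypertension[tl$patient_id == "p2"],
               as.Date("2014-03-01"))
  # p3 has no matching events at all
  expect_true(is.na(tl$first_diabetes[tl$patient_id == "p3"]))
  expect_true(is.na(tl$first_hypertension[tl$patient_id == "p3"]))
  expect_true(is.na(tl$first_ecvd[tl$patient_id == "p3"]))
})

test_that("a single elevated blood pressure does not satisfy a two-reading rule", {
  t <- tiny_emr_tables()
  t$prescriptions <- t$prescriptions[t$prescriptions$patient_id != "p2", ]
  t$encounters$icpc2_code[t$encounters$patient_id == "p2"] <- ""
  ds <- read_emr_tables(write_tiny_emr(tables = t))
  tl <- label_conditions(ds)
  # p1 has exactly one BP reading at 142/91 -> not hypertension
  expect_true(is.na(tl$first_hypertension[tl$patient_id == "p1"]))
  # add a second elevated reading: hypertension dates from the second one
  t$vitals <- rbind(t$vitals, data.frame(
    patient_id = "p1", date = "2015-02-01", systolic_bp = "150",
    diastolic_bp = "85", bmi = "", weight = "", height = ""))
  ds2 <- read_emr_tables(write_tiny_emr(tables = t))
  tl2 <- label_conditions(ds2)
  expect_equal(tl2$first_hypertension[tl2$patient_id == "p1"],
               as.Date("2015-02-01"))
})

test_that("engine agrees with a brute-force scan on randomized fixtures", {
  set.seed(1234)
  rules <- load_rule_set()
  gen <- generate_emr(simulation_config(n_gps = 4, patients_per_gp = 12,
                                        seed = 77))
  ds <- gen$dataset
  tl <- label_conditions(ds, rules)
  ids <- sample(ds$patients$patient_id, 30)
  for (id in ids) {
    enc <- ds$encounters[ds$encounters$patient_id == id, ]
    rx <- ds$prescriptions[ds$prescriptions$patient_id == id, ]
    labs <- ds$labs[ds$labs$patient_id == id, ]
    vit <- ds$vitals[ds$vitals$patient_id == id, ]
    for (cond in c("diabetes", "hypertension", "ecvd")) {
      want <- oracle_first_condition(rules, cond, enc, rx, labs, vit)
      got <- tl[[paste0("first_", cond)]][tl$patient_id == id]
      expect_equal(got, want, info = paste(id, cond))
    }
  }
})

test_that("adding events never removes or postpones first evidence", {
  rules <- load_rule_set()
  gen <- generate_emr(simulation_config(n_gps = 3, patients_per_gp = 10,
                                        seed = 5))
  ds <- gen$dataset
  tl1 <- label_conditions(ds, rules)
  # graft extra qualifying events onto every patient late in the window
  extra <- tibble::tibble(patient_id = ds$patients$patient_id,
                          date = as.Date("2019-11-30"),
                          atc_code = "A10BA02", end_date = as.Date(NA))
  ds2 <- ds
  ds2$prescriptions <- dplyr::bind_rows(ds$prescriptions, extra)
  tl2 <- label_conditions(ds2, rules)
  had <- !is.na(tl1$first_diabetes)
  expect_true(all(!is.na(tl2$first_diabetes)))
  expect_true(all(tl2$first_diabetes[had] <= tl1$first_diabetes[had]))
  expect_equal(tl2$first_hypertension, tl1$first_hypertension)
})
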