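# Small in-code fixtures shared across test files.

tiny_emr_tables <- function() {
  list(
    patients = data.frame(
      patient_id = c("p1", "p2", "p3"),
      gp_id = c("g1", "g1", "g1"),
      gender = c("female", "male", "female"),
      birth_year = c(1950L, 1940L, 1975L)
    ),
    gps = data.frame(
      gp_id = "g1", gender = "male", birth_year = 1965L,
      urban_location = "true"
    ),
    encounters = data.frame(
      patient_id = c("p1", "p1", "p2", "p3"),
      date = c("2014-01-10", "2015-06-01", "2014-03-01", "2016-02-02"),
      icpc2_code = c("", "", "K86", "")
    ),
    prescriptions = data.frame(
      patient_id = c("p1", "p2"),
      date = c("2014-02-01", "2014-03-01"),
      atc_code = c("A10BA02", "C09AA05"),
      end_date = c("", "2014-09-01")
    ),
    labs = data.frame(
      patient_id = c("p1", "p1", "p2", "p3"),
      date = c("2014-01-10", "2014-06-01", "2014-03-01", "2016-02-02"),
      analyte = c("serum_creatinine", "serum_creatinine", "acr", "hba1c"),
      value = c("95", "110", "4.2", "5.6"),
      unit = c("umol/l", "umol/l", "mg/mmol", "%")
    ),
    vitals = data.frame(
      patient_id = c("p1", "p2"),
      date = c("2014-01-10", "2014-03-01"),
      systolic_bp = c("142", "128"),
      diastolic_bp = c("91", "79"),
      bmi = c("", "24.2"), weight = c("", ""), height = c("", "")
    )
  )
}

write_tiny_emr <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                           tables = tiny_emr_tables()) {
  paths <- list()
  for (tab in names(tables)) {
    paths[[tab]] <- file.path(dir, paste0(tab, ".csv"))
    readr::write_csv(tables[[tab]], paths[[tab]], progress = FALSE)
  }
  paths
}

# a compact but complete in-memory dataset built through the constructor
tiny_emr_dataset <- function() {
  t <- tiny_emr_tables()
  read_emr_tables(write_tiny_emr(tables = t))
}
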