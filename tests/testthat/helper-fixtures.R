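# Small deterministic fixtures built in code.

# A hand-written six-patient cohort covering normal and deranged vitals.
demo_records <- function() {
  data.frame(
    patient_id = paste0("P", 1:6),
    age = c(38, 55, 27, 60, 45, 33),
    sex = c("male", "female", "male", "male", "female", "male"),
    sbp = c(110, 100, 90, 120, 80, 100),
    dbp = c(70, 60, 50, 80, 40, 65),
    pulse = c(80, 108, 110, 60, 135, 95),
    resp_rate = c(14, 28, 30, 12, 35, 22),
    temperature = c(36.5, 37.0, 38.5, 37.0, 34.0, 39.0),
    gcs = c(15, 15, 13, 15, 7, 14),
    wbc = c(8.0, 4.7, 3.2, 8.0, 15.0, NA),
    platelets = c(250, 160, 90, 300, 60, 180),
    band_forms_pct = c(2, NA, 12, 1, 20, NA),
    suspected_infection = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    died_in_hospital = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

demo_cohort <- function() cohort(demo_records(), label = "demo")

# Random valid records for property-style tests.
random_records <- function(n, seed) {
  set.seed(seed)
  sbp <- round(runif(n, 60, 220))
  dbp <- pmin(round(runif(n, 30, 110)), sbp - 1)
  data.frame(
    patient_id = sprintf("R%04d", seq_len(n)),
    age = round(runif(n, 18, 90)),
    sex = sample(c("male", "female"), n, TRUE),
    sbp = sbp, dbp = dbp,
    pulse = round(runif(n, 40, 180)),
    resp_rate = round(runif(n, 8, 60)),
    temperature = round(runif(n, 33, 41.5), 1),
    gcs = sample(3:15, n, TRUE),
    wbc = round(runif(n, 0.5, 30), 1),
    platelets = round(runif(n, 10, 600)),
    band_forms_pct = round(runif(n, 0, 40)),
    suspected_infection = sample(c(TRUE, FALSE), n, TRUE),
    died_in_hospital = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE
  )
}
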