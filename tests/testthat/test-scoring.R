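test_that("proposed index scores the printed bands with maximum 5", {
  idx <- proposed_index()
  expect_equal(idx$max_score, 5L)

  # boundary behaviour exactly at the printed cutoffs
  rec <- function(sbp, dbp, pulse, rr, temp, gcs) {
    data.frame(patient_id = "x", sbp = sbp, dbp = dbp, pulse = pulse,
               resp_rate = rr, temperature = temp, gcs = gcs)
  }
  # map 109.9 -> 0 points, 110.0 -> 1 (sbp/dbp chosen to hit map exactly)
  expect_equal(score_cohort(rec(169.9, 80, 80, 20, 37, 15), idx), 0L)
  expect_equal(score_cohort(rec(170, 80, 80, 20, 37, 15), idx), 1L)
  # temperature 35.6 -> 0, 35.5 -> 1; 38.6 -> 1
  expect_equal(score_cohort(rec(100, 70, 80, 20, 35.6, 15), idx), 0L)
  expect_equal(score_cohort(rec(100, 70, 80, 20, 35.5, 15), idx), 1L)
  expect_equal(score_cohort(rec(100, 70, 80, 20, 38.6, 15), idx), 1L)
  # every band abnormal -> 5
  expect_equal(score_cohort(rec(75, 60, 110, 32, 39.0, 12), idx), 5L)
  # development-cohort medians score 1 (pulse only)
  expect_equal(score_cohort(rec(100, 60, 108, 28, 37.0, 15), idx), 1L)
})

test_that("MEWS matches the printed enumeration with maximum 14", {
  mews <- mews_index()
  expect_equal(mews$max_score, 14L)
  rec <- function(sbp, dbp, pulse, rr, temp, gcs) {
    data.frame(patient_id = "x", sbp = sbp, dbp = dbp, pulse = pulse,
               resp_rate = rr, temperature = temp, gcs = gcs)
  }
  # all reference bands -> 0
  expect_equal(score_cohort(rec(110, 70, 80, 14, 36.5, 15), mews), 0L)
  # worst bands -> 3+3+3+2+3 = 14
  expect_equal(score_cohort(rec(65, 40, 135, 35, 34.0, 7), mews), 14L)
  # GCS 14 earns exactly 1 point
  expect_equal(score_cohort(rec(110, 70, 80, 14, 36.5, 14), mews), 1L)
  # shared boundaries go to the higher-severity band: sbp 80 -> 2, 100 -> 1
  expect_equal(score_cohort(rec(80, 40, 80, 14, 36.5, 15), mews), 2L)
  expect_equal(score_cohort(rec(100, 60, 80, 14, 36.5, 15), mews), 1L)
  # pulse below 40 is not scored in this enumeration
  expect_equal(score_cohort(rec(110, 70, 38, 14, 36.5, 15), mews), 0L)
  expect_match(mews$components$pulse$note, "not assigned")
})

test_that("every value in a variable's domain maps to exactly one band", {
  set.seed(31)
  for (idx in list(proposed_index(), mews_index())) {
    for (co in idx$components) {
      dom <- c(list(resp_rate = c(0.1, 200), pulse = c(0.1, 300),
                    map = c(0.1, 400), sbp = c(0.1, 400),
                    temperature = c(25, 45), gcs = c(3, 15))[[co$variable]])
      vals <- c(runif(300, dom[1], dom[2]), dom,
                vapply(co$bands, `[[`, 0, "lower"),
                vapply(co$bands, `[[`, 0, "upper"))
      vals <- vals[vals >= dom[1] & vals <= dom[2]]
      hits <- vapply(vals, function(v) {
        sum(vapply(co$bands, function(b) {
          lo <- if (b$lower_closed) v >= b$lower else v > b$lower
          hi <- if (b$upper_closed) v <= b$upper else v < b$upper
          lo && hi
        }, TRUE))
      }, 0L)
      expect_true(all(hits == 1L), label = paste(idx$name, co$variable))
    }
  }
})

test_that("scoring is deterministic and refuses missing variables", {
  co <- demo_cohort()
  expect_identical(score_cohort(co), score_cohort(co))
  broken <- demo_records()
  broken$gcs <- NULL
  expect_error(score_cohort(cbind(broken, gcs = NA_real_)), "gcs")
})

test_that("score distributions tabulate patients and deaths per score", {
  co <- demo_cohort()
  dist <- score_distribution(co)
  expect_s3_class(dist, "vi_score_dist")
  expect_equal(sum(dist$n_patients), nrow(co))
  expect_equal(sum(dist$n_deaths), sum(co$died_in_hospital))
  expect_true(all(dist$n_deaths <= dist$n_patients))

  flat <- score_distribution_from_scores(rep(0L, 10), rep(FALSE, 10))
  expect_equal(nrow(flat), 1L)
  expect_equal(flat$n_patients, 10L)
})

test_that("index definitions survive a JSON round-trip", {
  path <- withr::local_tempfile(fileext = ".json")
  for (idx in list(proposed_index(), mews_index())) {
    write_index_json(idx, path)
    back <- read_index_json(path)
    expect_equal(back$max_score, idx$max_score)
    co <- cohort(random_records(40, seed = 8), label = "r")
    expect_identical(score_cohort(co, back), score_cohort(co, idx))
  }
})
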