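test_that("generation is deterministic given the seed and leaves the RNG alone", {
  cfg <- generator_config(400, 17)
  set.seed(99)
  before <- .Random.seed
  a <- generate_cohort(cfg)
  expect_identical(.Random.seed, before)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(generator_config(400, 18))
  expect_false(identical(a$pulse, c$pulse))
})

test_that("every generated record satisfies the record invariants", {
  co <- generate_cohort(generator_config(2000, 5))
  expect_equal(nrow(validate_records(co)), 0L)
  expect_true(all(co$dbp < co$sbp))
  expect_true(all(co$gcs %in% 3:15))
})

test_that("the calibrated intercept hits the target mortality", {
  co <- generate_cohort(generator_config(4000, 23))
  expect_lt(abs(attr(co, "expected_mortality") - 0.23), 0.005)
  expect_lt(abs(mean(co$died_in_hospital) - 0.23), 0.03)
  lowrisk <- generate_cohort(generator_config(
    2000, 23, risk = default_risk_model(target_mortality = 0.05)))
  expect_lt(abs(attr(lowrisk, "expected_mortality") - 0.05), 0.005)
})

test_that("null configurations make death independent of the vitals", {
  co <- generate_cohort(generator_config(4000, 29,
                                         risk = default_risk_model(null = TRUE)))
  hi <- co$pulse >= 100
  expect_lt(abs(mean(co$died_in_hospital[hi]) -
                  mean(co$died_in_hospital[!hi])), 0.04)
  expect_equal(length(planted_cutoffs(generator_config(
    100, 1, risk = default_risk_model(null = TRUE)))), 0L)
})

test_that("planted cutoffs are the published ones", {
  expect_equal(
    planted_cutoffs(generator_config(100, 1)),
    c(resp_rate = 30, pulse = 100, map_low = 70, map_high = 110,
      temperature_low = 35.6, temperature_high = 38.6)
  )
})

test_that("score-table reconstruction emits the printed patient and death totals", {
  dev <- reconstruct_from_score_table(table4_scores("development"))
  expect_equal(nrow(dev), 167L)
  expect_equal(sum(dev$died), 39L)
  val <- reconstruct_from_score_table(table4_scores("validation"))
  expect_equal(nrow(val), 150L)
  expect_equal(sum(val$died), 45L)
  single <- reconstruct_from_score_table(
    data.frame(score = 0, n_patients = 5, died_pct = 0))
  expect_equal(nrow(single), 5L)
  expect_equal(sum(single$died), 0L)
})

test_that("simulated marginals land on the published medians", {
  co <- generate_cohort(generator_config(10000, 7))
  t1 <- table1_medians("development")
  tgt <- function(v) t1$median[t1$variable == v]
  expect_lt(abs(median(co$pulse) - tgt("pulse")) / tgt("pulse"), 0.05)
  expect_lt(abs(median(co$resp_rate) - tgt("resp_rate")) / tgt("resp_rate"), 0.05)
  expect_lt(abs(median(co$temperature) - 37), 0.3)
  m <- median(mean_arterial_pressure(co$sbp, co$dbp))
  expect_true(m >= 69 && m <= 77)
  expect_lt(abs(median(co$wbc) - 4.7) / 4.7, 0.05)
  expect_lt(abs(median(co$platelets) - 160) / 160, 0.05)
  # IQR endpoints within 15% of the published ones
  q <- quantile(co$pulse, c(0.25, 0.75))
  expect_lt(abs(q[[1]] - 90) / 90, 0.15)
  expect_lt(abs(q[[2]] - 120) / 120, 0.15)
  # altered mental state prevalence near the published 21%
  expect_lt(abs(mean(co$gcs <= 14) - 0.20), 0.03)
})
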