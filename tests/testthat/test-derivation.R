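# Simulation oracles for the spline risk-curve machinery. Cohorts are
# built from the generator with known risk structure.

sim_cohort <- function(n, seed, risk = default_risk_model()) {
  generate_cohort(generator_config(n, seed, risk = risk))
}

test_that("null-risk cohorts give a flat curve near the mortality rate", {
  co <- sim_cohort(2000, seed = 301,
                   risk = default_risk_model(target_mortality = 0.25,
                                             null = TRUE))
  cv <- fit_risk_curve(co, "pulse")
  mid <- cv$grid >= quantile(co$pulse, 0.2) & cv$grid <= quantile(co$pulse, 0.8)
  expect_true(all(abs(cv$p_death[mid] - 0.25) < 0.05))
})

test_that("with a linear logit the spline agrees with the plain logistic fit", {
  set.seed(302)
  n <- 2000
  x <- rnorm(n, 50, 10)
  y <- runif(n) < plogis(-1.2 + 0.04 * (x - 50))
  co <- cohort(data.frame(
    patient_id = sprintf("L%04d", 1:n), sbp = 120, dbp = 80,
    pulse = round(pmax(x, 31)), resp_rate = 18, temperature = 37,
    gcs = 15, suspected_infection = TRUE, died_in_hospital = y
  ), label = "linear")
  knots <- unname(quantile(co$pulse, c(0.05, 0.35, 0.65, 0.95)))
  cv <- fit_risk_curve(co, "pulse", knots = knots)
  plain <- glm(y ~ pulse, binomial(), data = co)
  inside <- cv$grid >= min(knots) & cv$grid <= max(knots)
  p_plain <- predict(plain, data.frame(pulse = cv$grid[inside]),
                     type = "response")
  expect_true(all(abs(cv$p_death[inside] - p_plain) < 0.02))
})

test_that("no spurious nonlinearity: spline vs linear deviance gap is chi-square sized", {
  set.seed(303)
  exceed <- 0
  for (i in 1:10) {
    n <- 1500
    x <- rnorm(n, 50, 10)
    y <- runif(n) < plogis(-1.2 + 0.04 * (x - 50))
    co <- cohort(data.frame(
      patient_id = sprintf("L%04d", 1:n), sbp = 120, dbp = 80,
      pulse = round(pmax(x, 31)), resp_rate = 18, temperature = 37,
      gcs = 15, suspected_infection = TRUE, died_in_hospital = y
    ), label = "linear")
    cv <- fit_risk_curve(co, "pulse", refine = FALSE)
    plain <- glm(y ~ pulse, binomial(), data = co)
    gap <- deviance(plain) - deviance(cv$fit)
    df <- length(coef(cv$fit)) - 2
    if (gap > qchisq(0.95, df)) exceed <- exceed + 1
  }
  expect_lte(exceed, 1)
})

test_that("U-shaped risk yields low/reference/high categories with a sane middle", {
  co <- sim_cohort(5000, seed = 304)
  cs <- derive_categories(fit_risk_curve(co, "map"), co)
  cats <- cs$categories
  expect_gte(nrow(cats), 3L)
  expect_false(cats$is_reference[1])
  expect_false(cats$is_reference[nrow(cats)])
  expect_true(any(cats$is_reference))
  ref <- which(cats$is_reference)
  expect_lt(min(cats$mortality[ref]), min(cats$mortality[-ref]))
  expect_equal(sum(cats$n), nrow(co))
  expect_equal(sum(cats$deaths), sum(co$died_in_hospital))
})

test_that("hinge-shaped respiratory risk puts the boundary near the planted cutoff", {
  co <- sim_cohort(5000, seed = 305)
  cs <- derive_categories(fit_risk_curve(co, "resp_rate"), co)
  cuts <- category_cutoffs(cs)
  expect_gte(length(cuts), 1L)
  expect_lte(min(abs(cuts - 30)), 2)
})

test_that("null cohorts produce a single flagged reference category", {
  co <- sim_cohort(3000, seed = 306, risk = default_risk_model(null = TRUE))
  cs <- derive_categories(fit_risk_curve(co, "temperature"), co)
  expect_true(all(cs$categories$is_reference))
  expect_true(nzchar(cs$flag))
  expect_equal(length(category_cutoffs(cs)), 0L)
})

test_that("extract_cutoffs builds one-point bands over full domains", {
  co <- sim_cohort(5000, seed = 307)
  deriv <- derive_index(co)
  idx <- deriv$index
  expect_s3_class(idx, "vi_index")
  expect_true(all(c("map", "resp_rate", "gcs") %in% names(idx$components)))
  for (comp in idx$components) {
    pts <- vapply(comp$bands, `[[`, 0L, "points")
    expect_true(all(pts %in% 0:1))
  }
  # scoring with the derived index works on the cohort that produced it
  expect_true(all(score_cohort(co, idx) <= idx$max_score))
  # flagged-flat variables are excluded entirely
  expect_null(extract_cutoffs(list(
    derive_categories(fit_risk_curve(
      sim_cohort(3000, seed = 308, risk = default_risk_model(null = TRUE)),
      "pulse"),
      sim_cohort(3000, seed = 308, risk = default_risk_model(null = TRUE)))
  )))
})

test_that("the GCS component is derived categorically at the planted effect", {
  co <- sim_cohort(5000, seed = 309)
  comp <- derive_gcs_component(co)
  expect_s3_class(comp, "vi_component")
  # altered mental state (<=14) scores 1, normal GCS scores 0
  expect_equal(component_points <- vapply(comp$bands, `[[`, 0L, "points"),
               c(1L, 0L))
  expect_equal(comp$bands[[1]]$upper, 15)
  expect_null(derive_gcs_component(
    sim_cohort(3000, seed = 310, risk = default_risk_model(null = TRUE))))
})

test_that("small cohorts are refused", {
  co <- sim_cohort(60, seed = 311)
  expect_error(fit_risk_curve(co[1:30, ], "pulse"), "at least 50")
})
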