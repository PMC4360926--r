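dev_distribution <- function() {
  rows <- table4_scores("development")
  recs <- reconstruct_from_score_table(rows)
  score_distribution_from_scores(recs$score, recs$died, label = "development")
}

val_distribution <- function() {
  rows <- table4_scores("validation")
  recs <- reconstruct_from_score_table(rows)
  score_distribution_from_scores(recs$score, recs$died, label = "validation")
}

test_that("death counts are reconstructed by rounding half away from zero", {
  expect_equal(reconstruct_deaths(57, 25), 14L)   # 14.25
  expect_equal(reconstruct_deaths(36, 36), 13L)   # 12.96
  expect_equal(reconstruct_deaths(2, 100), 2L)
  expect_equal(reconstruct_deaths(0, 50), 0L)
  expect_equal(reconstruct_deaths(32, 6.3), 2L)   # 2.016
  expect_error(reconstruct_deaths(1, 101))
})

test_that("dichotomizing the reconstructed tables gives the published 2x2 cells", {
  tab_dev <- dichotomize(dev_distribution(), 3)
  expect_equal(c(tab_dev$a, tab_dev$b, tab_dev$c, tab_dev$d),
               c(20, 30, 19, 98))
  tab_val <- dichotomize(val_distribution(), 3)
  expect_equal(c(tab_val$a, tab_val$b, tab_val$c, tab_val$d),
               c(31, 52, 14, 53))
  expect_warning(dichotomize(dev_distribution(), 0), "empty arm")
})

test_that("Woolf odds ratios reproduce the published statistics at display precision", {
  res_dev <- odds_ratio_woolf(two_by_two(20, 30, 19, 98))
  expect_equal(res_dev$odds_ratio, 20 * 98 / (30 * 19), tolerance = 1e-12)
  f <- format_association(res_dev)
  expect_equal(unname(f["or_ci"]), "3.4 (1.6 to 7.3)")
  expect_equal(unname(f["p"]), "0.001")

  res_val <- odds_ratio_woolf(two_by_two(31, 52, 14, 53))
  f2 <- format_association(res_val)
  expect_equal(unname(f2["or_ci"]), "2.3 (1.1 to 4.7)")
  expect_equal(unname(f2["p"]), "0.031")
  # sub-1 estimates print with 2 significant figures
  f3 <- format_association(odds_ratio_woolf(two_by_two(14, 53, 31, 52)))
  expect_match(unname(f3["or_ci"]), "^0.44 ")
})

test_that("balanced tables give OR 1 with a log-symmetric interval", {
  for (k in c(3, 10, 57)) {
    res <- odds_ratio_woolf(two_by_two(k, k, k, k))
    expect_equal(res$odds_ratio, 1)
    expect_equal(res$ci_low * res$ci_high, 1, tolerance = 1e-12)
    expect_equal(res$p_value, 1)
  }
})

test_that("swapping exposure rows inverts the odds ratio and interval", {
  set.seed(41)
  for (i in 1:20) {
    cells <- sample(1:80, 4, replace = TRUE)
    r1 <- odds_ratio_woolf(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    r2 <- odds_ratio_woolf(two_by_two(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(r1$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-12)
    expect_equal(r1$ci_low, 1 / r2$ci_high, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  }
})

test_that("the Woolf OR equals the logistic-regression coefficient", {
  set.seed(42)
  for (i in 1:25) {
    cells <- sample(1:200, 4, replace = TRUE)
    res <- odds_ratio_woolf(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    fit <- glm(cbind(deaths, surv) ~ exposed,
               data = data.frame(exposed = c(1, 0),
                                 deaths = cells[c(1, 3)],
                                 surv = cells[c(2, 4)]),
               family = binomial(),
               control = glm.control(epsilon = 1e-12))
    expect_equal(log(res$odds_ratio), unname(coef(fit)[2]), tolerance = 1e-6)
  }
})

test_that("p-value and confidence interval agree on significance", {
  set.seed(43)
  for (i in 1:50) {
    cells <- sample(1:60, 4, replace = TRUE)
    res <- odds_ratio_woolf(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    excludes_one <- res$ci_low > 1 || res$ci_high < 1
    expect_equal(res$p_value < 0.05, excludes_one)
  }
})

test_that("zero cells error unless the Haldane correction is requested", {
  tab <- two_by_two(0, 10, 5, 10)
  expect_error(odds_ratio_woolf(tab), "zero cell")
  res <- odds_ratio_woolf(tab, correction = TRUE)
  expect_equal(res$method, "haldane_corrected")
  expect_equal(res$odds_ratio, (0.5 * 10.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("category mortality partitions the cohort", {
  co <- cohort(random_records(300, seed = 44), label = "r")
  tab <- category_mortality(co, "map", c(-Inf, 70, 110, Inf))
  expect_equal(sum(tab$n), 300L)
  expect_equal(sum(tab$deaths), sum(co$died_in_hospital))
  one <- category_mortality(co, "pulse", c(-Inf, Inf))
  expect_equal(one$mortality_pct, 100 * mean(co$died_in_hospital))
  expect_error(category_mortality(co, "pulse", c(60, 100)), "cover")
})

test_that("overall mortality matches the published percentages", {
  dev <- overall_mortality(dev_distribution())
  expect_equal(dev$percent, 100 * 39 / 167, tolerance = 1e-12)
  expect_equal(dev$percent_rounded, 23L)
  val <- overall_mortality(val_distribution())
  expect_equal(val$percent_rounded, 30L)
  expect_equal(val$percent, 30)
  none <- overall_mortality(
    score_distribution_from_scores(c(0L, 1L), c(FALSE, FALSE)))
  expect_equal(none$percent, 0)
})
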