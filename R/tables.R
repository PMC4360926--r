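# Published summary tables used as inputs: per-score mortality rows and
# admission-characteristics medians/IQRs for the two Ugandan sepsis cohorts
# (167 development patients, 2011; 150 validation patients, 2009).

#' Published per-score mortality rows
#'
#' The per-score rows ("number of patients" and "died (%)") of the proposed
#' index for the development and validation cohorts, as printed. These rows
#' are the only patient-level information available for reproducing the
#' published score-performance statistics; per-patient records are rebuilt
#' from them with [reconstruct_from_score_table()].
#'
#' @param cohort `"development"` or `"validation"`.
#' @return data.frame with `score`, `n_patients`, `died_pct`.
#' @export
table4_scores <- function(cohort = c("development", "validation")) {
  cohort <- match.arg(cohort)
  if (cohort == "development") {
    data.frame(
      score = 0:5,
      n_patients = c(28L, 32L, 57L, 36L, 12L, 2L),
      died_pct = c(11, 6.3, 25, 36, 42, 100)
    )
  } else {
    data.frame(
      score = 0:5,
      n_patients = c(3L, 26L, 38L, 59L, 18L, 6L),
      died_pct = c(33, 27, 16, 34, 33, 83)
    )
  }
}

#' Published admission-vitals medians and interquartile ranges
#'
#' Numeric admission characteristics (median and IQR) of the development and
#' validation cohorts, used to calibrate the synthetic-cohort generator's
#' marginal distributions.
#'
#' @param cohort `"development"` or `"validation"`.
#' @return data.frame with `variable`, `median`, `q1`, `q3`.
#' @export
table1_medians <- function(cohort = c("development", "validation")) {
  cohort <- match.arg(cohort)
  vars <- c("age", "pulse", "temperature", "resp_rate", "sbp", "dbp",
            "map", "wbc", "platelets")
  if (cohort == "development") {
    data.frame(
      variable = vars,
      median = c(38, 108, 37, 28, 100, 60, 73, 4.7, 160),
      q1 = c(28, 90, 36.5, 22, 90, 50, 63, 2.7, 108),
      q3 = c(55, 120, 38.3, 32, 120, 70, 87, 6.2, 229),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      variable = vars,
      median = c(31, 110, 38.5, 30, 110, 60, 73, 5.7, 164),
      q1 = c(25, 104, 38, 24, 85, 50, 63, 3.2, 88),
      q3 = c(41, 120, 39, 36, 110, 70, 88, 9.2, 252),
      stringsAsFactors = FALSE
    )
  }
}
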