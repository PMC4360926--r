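# Contingency statistics: 2x2 tables from score distributions, Woolf
# (log-odds Wald) odds ratios with confidence intervals and p-values,
# category mortality tables, and overall mortality.

#' 2x2 exposure-by-outcome table
#'
#' @param a deaths among exposed.
#' @param b survivors among exposed.
#' @param c deaths among unexposed.
#' @param d survivors among unexposed.
#' @param exposure_label,outcome_label descriptive labels.
#' @return list of class `vi_two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, exposure_label = "exposed",
                       outcome_label = "died") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stopf("2x2 cell counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0) {
    warnf("2x2 table has an empty arm; odds ratio is not estimable")
  }
  structure(list(a = a, b = b, c = c, d = d,
                 exposure_label = exposure_label,
                 outcome_label = outcome_label),
            class = "vi_two_by_two")
}

#' @export
print.vi_two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c(x$exposure_label,
                                paste("not", x$exposure_label)),
                              c(x$outcome_label,
                                paste("not", x$outcome_label))))
  print(m)
  invisible(x)
}

#' Reconstruct a death count from a printed percentage
#'
#' Per-score death counts are recovered from printed "n (died %)" table
#' rows as `n * pct / 100` rounded half away from zero.
#'
#' @param n_patients number of patients in the row.
#' @param mortality_pct printed percentage dying (0-100).
#' @return integer death count.
#' @export
#' @examples
#' reconstruct_deaths(57, 25)  # 14
#' reconstruct_deaths(2, 100)  # 2
reconstruct_deaths <- function(n_patients, mortality_pct) {
  stopifnot(all(n_patients >= 0), all(mortality_pct >= 0),
            all(mortality_pct <= 100))
  deaths <- round_half_away(n_patients * mortality_pct / 100)
  bad <- which(deaths > n_patients)
  if (length(bad) > 0) {
    stopf("reconstructed deaths (%d) exceed patients (%d) at row %d",
          deaths[bad[1]], n_patients[bad[1]], bad[1])
  }
  as.integer(deaths)
}

#' Dichotomize a score distribution at a threshold
#'
#' Splits a per-score table into exposed (score >= threshold) versus
#' unexposed (score < threshold) and returns the 2x2 death table.
#'
#' @param distribution a `vi_score_dist`.
#' @param threshold integer score threshold.
#' @return a `vi_two_by_two`.
#' @export
dichotomize <- function(distribution, threshold) {
  stopifnot(inherits(distribution, "vi_score_dist"))
  hi <- distribution$score >= threshold
  a <- sum(distribution$n_deaths[hi])
  b <- sum(distribution$n_patients[hi]) - a
  c <- sum(distribution$n_deaths[!hi])
  d <- sum(distribution$n_patients[!hi]) - c
  two_by_two(a, b, c, d,
             exposure_label = sprintf("score >= %d", threshold),
             outcome_label = "died in hospital")
}

#' Woolf odds ratio with Wald confidence interval and p-value
#'
#' Computes OR = ad/bc with the Woolf (log-odds Wald) interval
#' exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)) and a two-sided normal
#' p-value for ln OR / SE. With `correction = TRUE`, a Haldane-Anscombe
#' +0.5 is added to every cell when any cell is zero (off by default: a
#' zero cell is then an error, so silent corrections never distort a
#' reproduction).
#'
#' @param table a `vi_two_by_two`.
#' @param z normal quantile for the confidence interval (1.96 for 95%).
#' @param correction apply Haldane-Anscombe +0.5 on zero cells.
#' @return list of class `vi_association`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `se_log_or`, `method`, `table`.
#' @export
odds_ratio_woolf <- function(table, z = 1.96, correction = FALSE) {
  stopifnot(inherits(table, "vi_two_by_two"))
  cells <- c(table$a, table$b, table$c, table$d)
  method <- "woolf"
  if (any(cells == 0)) {
    if (!correction) {
      stopf("2x2 table has a zero cell; enable `correction` for Haldane-Anscombe +0.5")
    }
    cells <- cells + 0.5
    method <- "haldane_corrected"
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(
    list(
      odds_ratio = exp(log_or),
      ci_low = exp(log_or - z * se),
      ci_high = exp(log_or + z * se),
      p_value = 2 * stats::pnorm(-abs(log_or / se)),
      se_log_or = se,
      method = method,
      table = table
    ),
    class = "vi_association"
  )
}

#' Format an odds ratio / CI / p-value for display
#'
#' OR and CI bounds are shown to 1 decimal place (2 significant figures
#' below 1); p-values to 3 decimals.
#'
#' @param result a `vi_association`.
#' @return named character vector with `or_ci` (e.g. "3.4 (1.6 to 7.3)")
#'   and `p` (e.g. "0.001").
#' @export
format_association <- function(result) {
  stopifnot(inherits(result, "vi_association"))
  fmt1 <- function(x) {
    if (x < 1) format(signif(x, 2)) else sprintf("%.1f", x)
  }
  p <- result$p_value
  c(or_ci = sprintf("%s (%s to %s)", fmt1(result$odds_ratio),
                    fmt1(result$ci_low), fmt1(result$ci_high)),
    p = if (p < 5e-4) "<0.001" else sprintf("%.3f", p))
}

#' @export
print.vi_association <- function(x, ...) {
  f <- format_association(x)
  cat(sprintf("<vi_association> %s vs %s\n", x$table$exposure_label,
              x$table$outcome_label))
  cat(sprintf("  OR (95%% CI): %s, P = %s  [%s]\n", f["or_ci"], f["p"],
              x$method))
  invisible(x)
}

#' Observed mortality within fixed intervals of a vital sign
#'
#' Assigns every record to exactly one interval of `variable` (MAP computed
#' from sbp/dbp) and tabulates patients, deaths, and percent mortality per
#' interval.
#'
#' @param records a `vi_cohort`.
#' @param variable variable name (one of the scorable variables).
#' @param breaks ascending numeric cut points; intervals are
#'   `[break_i, break_{i+1})` and must cover every observed value. Use
#'   `-Inf`/`Inf` for open ends.
#' @return data.frame with `interval`, `lower`, `upper`, `n`, `deaths`,
#'   `mortality_pct`.
#' @export
category_mortality <- function(records, variable, breaks) {
  x <- if (variable == "map") {
    mean_arterial_pressure(records$sbp, records$dbp)
  } else {
    records[[variable]]
  }
  if (is.null(x)) stopf("variable '%s' not present", variable)
  keep <- !is.na(x)
  x <- x[keep]
  died <- records$died_in_hospital[keep]
  breaks <- sort(breaks)
  if (any(x < breaks[1]) || any(x >= breaks[length(breaks)])) {
    stopf("breaks do not cover observed %s range [%s, %s]", variable,
          min(x), max(x))
  }
  bin <- findInterval(x, breaks)
  out <- data.frame(
    interval = sprintf("[%s, %s)", breaks[-length(breaks)], breaks[-1]),
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    n = vapply(seq_len(length(breaks) - 1), function(i) sum(bin == i), 0L),
    deaths = vapply(seq_len(length(breaks) - 1),
                    function(i) sum(died[bin == i]), 0L),
    stringsAsFactors = FALSE
  )
  out$mortality_pct <- ifelse(out$n > 0, 100 * out$deaths / out$n, NA_real_)
  out
}

#' Overall mortality of a score distribution
#'
#' @param distribution a `vi_score_dist`.
#' @return list with `percent` (exact) and `percent_rounded` (nearest
#'   integer percent).
#' @export
overall_mortality <- function(distribution) {
  stopifnot(inherits(distribution, "vi_score_dist"),
            sum(distribution$n_patients) > 0)
  pct <- 100 * sum(distribution$n_deaths) / sum(distribution$n_patients)
  list(percent = pct, percent_rounded = as.integer(round_half_away(pct)))
}
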