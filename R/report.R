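# Reporting: reproduction of the published score-performance statistics
# from the built-in per-score tables, and the end-to-end synthetic
# derive/validate pipeline.

#' Reproduce the published index-performance statistics
#'
#' Rebuilds per-patient (score, outcome) records from the built-in
#' per-score mortality rows for both cohorts, dichotomizes at score >= 3,
#' and computes the Woolf odds ratio, 95% CI, p-value, and overall
#' mortality for each cohort. The display-precision values are compared
#' with the published ones (development OR 3.4, CI 1.6 to 7.3, p 0.001,
#' mortality 23%; validation OR 2.3, CI 1.1 to 4.7, p 0.031, mortality
#' 30%) and any mismatch is recorded.
#'
#' @param threshold score threshold defining the exposed group (default 3).
#' @return list of class `vi_reproduction`: per-cohort `distribution`,
#'   `table`, `association`, `overall`, `formatted`, `expected`, and a
#'   top-level `matches` flag.
#' @export
reproduction_report <- function(threshold = 3) {
  expected <- list(
    development = c(or_ci = "3.4 (1.6 to 7.3)", p = "0.001", mortality = "23"),
    validation = c(or_ci = "2.3 (1.1 to 4.7)", p = "0.031", mortality = "30")
  )
  out <- lapply(c("development", "validation"), function(lab) {
    rows <- table4_scores(lab)
    recs <- reconstruct_from_score_table(rows, label = lab)
    dist <- score_distribution_from_scores(recs$score, recs$died, label = lab)
    tab <- dichotomize(dist, threshold)
    assoc <- odds_ratio_woolf(tab)
    overall <- overall_mortality(dist)
    fmt <- c(format_association(assoc),
             mortality = as.character(overall$percent_rounded))
    list(distribution = dist, table = tab, association = assoc,
         overall = overall, formatted = fmt, expected = expected[[lab]],
         matches = identical(unname(fmt), unname(expected[[lab]])))
  })
  names(out) <- c("development", "validation")
  out$threshold <- threshold
  out$matches <- out$development$matches && out$validation$matches
  class(out) <- "vi_reproduction"
  out
}

#' @export
print.vi_reproduction <- function(x, ...) {
  cat(sprintf("<vi_reproduction> proposed index, score >= %d vs 0-%d\n",
              x$threshold, x$threshold - 1))
  for (lab in c("development", "validation")) {
    r <- x[[lab]]
    cat(sprintf("  %-12s OR (95%% CI) %s, P = %s; overall mortality %s%%%s\n",
                lab, r$formatted["or_ci"], r$formatted["p"],
                r$formatted["mortality"],
                if (r$matches) "" else "  ** MISMATCH with published values **"))
  }
  invisible(x)
}

#' Run the reproduction and fail loudly on mismatch
#'
#' Convenience wrapper around [reproduction_report()] that prints the
#' report and raises an error listing any statistic that disagrees with
#' the published values.
#'
#' @param threshold score threshold (default 3).
#' @return the `vi_reproduction`, invisibly.
#' @export
run_reproduction <- function(threshold = 3) {
  rep <- reproduction_report(threshold)
  print(rep)
  if (!rep$matches) {
    diffs <- unlist(lapply(c("development", "validation"), function(lab) {
      r <- rep[[lab]]
      bad <- which(r$formatted != r$expected)
      sprintf("%s %s: got %s, published %s", lab, names(r$formatted)[bad],
              r$formatted[bad], r$expected[bad])
    }))
    stopf("reproduction mismatch:\n%s", paste("  ", diffs, collapse = "\n"))
  }
  invisible(rep)
}

#' End-to-end synthetic derive/score/validate pipeline
#'
#' Generates a synthetic development cohort, derives a prognostic index
#' from it, generates an independent synthetic validation cohort under the
#' same conditions (seed + 1), scores both cohorts with the derived index,
#' and computes the dichotomized Woolf odds ratios. Deterministic given
#' `seed`.
#'
#' @param n cohort size (>= 50; default 5000).
#' @param seed integer seed.
#' @param threshold score threshold for dichotomization (default 3).
#' @param config optional `vi_generator_config` template; `n`, `seed`, and
#'   label are overridden per cohort.
#' @param ... further arguments passed to [derive_index()].
#' @return list of class `vi_pipeline`: `derivation`, `index`,
#'   `planted`, `recovered_cutoffs`, and per-cohort `distribution`,
#'   `association`, `overall`.
#' @export
run_pipeline <- function(n = 5000, seed = 1, threshold = 3, config = NULL,
                         ...) {
  if (n < 50) stopf("pipeline needs at least 50 records per cohort (n = %d)", n)
  base <- config %||% generator_config(n, seed)
  dev_cfg <- generator_config(n, seed, marginals = base$marginals,
                              risk = base$risk, label = "development")
  val_cfg <- generator_config(n, seed + 1, marginals = base$marginals,
                              risk = base$risk, label = "validation")
  dev <- generate_cohort(dev_cfg)
  val <- generate_cohort(val_cfg)
  deriv <- derive_index(dev, ...)
  if (is.null(deriv$index)) {
    stopf("derivation stage found no prognostic interval; no index to validate")
  }
  per_cohort <- lapply(list(development = dev, validation = val), function(co) {
    dist <- score_distribution(co, deriv$index)
    list(distribution = dist,
         association = odds_ratio_woolf(dichotomize(dist, threshold)),
         overall = overall_mortality(dist))
  })
  structure(
    list(
      derivation = deriv,
      index = deriv$index,
      planted = planted_cutoffs(dev_cfg),
      recovered_cutoffs = lapply(deriv$category_sets, category_cutoffs),
      development = per_cohort$development,
      validation = per_cohort$validation,
      threshold = threshold,
      seed = seed, n = n
    ),
    class = "vi_pipeline"
  )
}

#' @export
print.vi_pipeline <- function(x, ...) {
  cat(sprintf("<vi_pipeline> n = %d per cohort, seed = %d\n", x$n, x$seed))
  if (length(x$planted) > 0) {
    cat("  planted cutoffs:  ",
        paste(sprintf("%s=%g", names(x$planted), x$planted), collapse = ", "),
        "\n")
  }
  for (v in names(x$recovered_cutoffs)) {
    cat(sprintf("  recovered %-12s %s\n", paste0(v, ":"),
                paste(x$recovered_cutoffs[[v]], collapse = ", ")))
  }
  for (lab in c("development", "validation")) {
    f <- format_association(x[[lab]]$association)
    cat(sprintf("  %-12s score >= %d: OR %s, P = %s; mortality %.1f%%\n",
                lab, x$threshold, f["or_ci"], f["p"],
                x[[lab]]$overall$percent))
  }
  invisible(x)
}
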