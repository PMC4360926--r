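# Development-cohort derivation: flexible spline risk curves of in-hospital
# death against each admission vital, segmentation into reference vs
# prognostic categories relative to sample-average mortality, and cutoff
# extraction into an index definition.

#' Measurement resolution per variable
#'
#' Grid spacing and cutoff rounding unit for each vital sign: 1 cycle/min,
#' 1 beat/min, 1 mmHg, 0.1 degrees C, 1 GCS unit.
#'
#' @return named numeric vector.
#' @export
default_resolutions <- function() {
  c(resp_rate = 1, pulse = 1, map = 1, sbp = 1, temperature = 0.1, gcs = 1)
}

variable_values <- function(records, variable) {
  if (variable == "map") {
    mean_arterial_pressure(records$sbp, records$dbp)
  } else {
    v <- records[[variable]]
    if (is.null(v)) stopf("variable '%s' not present in the records", variable)
    v
  }
}

#' Fit a spline risk curve of in-hospital death against one vital sign
#'
#' Fits a univariable logistic model of death on a restricted cubic spline
#' of the vital sign (maximum likelihood via [stats::glm()]) and evaluates
#' the predicted death probability at the variable's measurement
#' resolution over a grid spanning the central 99% of observed values
#' (0.5th to 99.5th percentile); spline predictions in the extreme tails
#' rest on almost no data and are unreliable, so they are not used for
#' categorization.
#'
#' Knots are equally spaced across the same central-99% span. Quantile
#' placement (the common default) concentrates knots where data are dense
#' and leaves single long segments across the sparse tails of skewed
#' vitals; equal spacing keeps enough flexibility in exactly the regions
#' where prognostic cutoffs tend to sit. With `refine = TRUE` the fit is
#' two-stage: a first pass locates the steepest section of the fitted
#' log-odds curve and two extra knots are inserted around it before
#' refitting, so sharp risk transitions are tracked without inflating the
#' degrees of freedom everywhere else.
#'
#' @param records a `vi_cohort`.
#' @param variable one of `resp_rate`, `pulse`, `map`, `temperature`, `sbp`.
#' @param k number of knots (default 7), equally spaced over the central
#'   99% of observed values.
#' @param knots optional explicit knot locations (overrides `k` and
#'   disables refinement).
#' @param refine add two knots around the steepest fitted section
#'   (default TRUE).
#' @return list of class `vi_risk_curve`: `variable`, `grid`, `p_death`,
#'   `knots`, `n_obs`, `sample_mortality`, `lrt_p` (likelihood-ratio test of
#'   the spline against an intercept-only model), `fit`.
#' @export
fit_risk_curve <- function(records, variable, k = 7, knots = NULL,
                           refine = TRUE) {
  x <- variable_values(records, variable)
  y <- records$died_in_hospital
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 50) {
    stopf("need at least 50 complete records to fit a risk curve (have %d)",
          length(x))
  }
  if (length(unique(y)) < 2) stopf("outcome has a single class; cannot fit")
  span <- unname(stats::quantile(x, c(0.005, 0.995), type = 7))
  explicit <- !is.null(knots)
  if (!explicit) {
    if (k < 3) stopf("restricted cubic splines need at least 3 knots")
    knots <- seq(span[1], span[2], length.out = k)
  }
  knots <- sort(unique(knots))
  if (length(knots) < 3) {
    stopf("fewer than 3 distinct knots for %s; the variable may be too discrete",
          variable)
  }
  do_fit <- function(kn) {
    fit <- suppressWarnings(
      stats::glm(y ~ rcs_basis(x, kn), family = stats::binomial(),
                 control = stats::glm.control(maxit = 100))
    )
    if (!fit$converged || anyNA(stats::coef(fit))) {
      stopf("spline fit for %s did not converge (possible separation); try fewer knots",
            variable)
    }
    fit
  }
  fit <- do_fit(knots)
  if (refine && !explicit) {
    # locate the two steepest, well-separated sections of the fitted
    # log-odds curve (e.g. both arms of a U) and add local knots there
    probe <- seq(span[1], span[2], length.out = 201)
    eta_p <- cbind(1, rcs_basis(probe, knots)) %*% stats::coef(fit)
    slope <- abs(diff(as.numeric(eta_p)))
    i1 <- which.max(slope)
    far <- abs(seq_along(slope) - i1) > 25
    i2 <- if (any(far)) which(far)[which.max(slope[far])] else NA_integer_
    h <- diff(knots[1:2])
    stars <- probe[c(i1, i2)]
    stars <- stars[!is.na(stars)]
    add <- pmin(pmax(c(stars - h / 3, stars + h / 3), span[1]), span[2])
    knots2 <- sort(unique(c(knots, add)))
    fit2 <- tryCatch(do_fit(knots2), error = function(e) NULL)
    if (!is.null(fit2)) {
      knots <- knots2
      fit <- fit2
    }
  }
  res <- default_resolutions()[[variable]]
  lo <- round(span[1] / res) * res
  hi <- round(span[2] / res) * res
  grid <- round(seq(lo, hi, by = res), 10)
  eta <- cbind(1, rcs_basis(grid, knots)) %*% stats::coef(fit)
  lrt <- fit$null.deviance - fit$deviance
  structure(
    list(
      variable = variable,
      grid = grid,
      p_death = as.numeric(stats::plogis(eta)),
      knots = knots,
      n_obs = length(x),
      sample_mortality = mean(y),
      lrt_p = stats::pchisq(lrt, df = length(stats::coef(fit)) - 1,
                            lower.tail = FALSE),
      fit = fit
    ),
    class = "vi_risk_curve"
  )
}

#' @export
print.vi_risk_curve <- function(x, ...) {
  cat(sprintf(
    "<vi_risk_curve> %s: n = %d, grid [%s, %s], %d knots, LRT p = %.3g\n",
    x$variable, x$n_obs, min(x$grid), max(x$grid), length(x$knots), x$lrt_p))
  invisible(x)
}

# Collapse runs shorter than `min_run` grid steps into their neighbours so
# single-point flickers of the fitted curve around the threshold do not
# fragment the categories.
smooth_runs <- function(flag, min_run) {
  repeat {
    r <- rle(flag)
    if (length(r$lengths) <= 1 || min(r$lengths) >= min_run) break
    i <- which.min(r$lengths)
    r$values[i] <- !r$values[i]
    flag <- inverse.rle(r)
  }
  flag
}

#' Segment a risk curve into reference and prognostic categories
#'
#' Grid runs where the model-predicted death probability exceeds the
#' sample-average mortality become prognostic intervals; complementary
#' runs (at or "about" the average) are reference. Before segmentation the
#' variable must show evidence of association with death: if the spline's
#' likelihood-ratio test p-value exceeds `alpha` the whole range is a
#' single reference category flagged `no_association` — without this
#' screen, any null curve's noise wiggles above the average would be read
#' as prognostic ranges. Each category is annotated with the observed (not
#' predicted) mortality of the records falling in it.
#'
#' @param curve a `vi_risk_curve`.
#' @param records the cohort the curve was fitted on.
#' @param tol optional tolerance above the sample average still counted as
#'   "about average" (probability scale, default 0).
#' @param alpha significance level for the association screen
#'   (default 0.01, roughly a 0.05 Bonferroni share across four vitals).
#' @param min_run minimum category width in grid steps (default 3).
#' @return list of class `vi_category_set`: `variable`, `categories`
#'   (data.frame `lower`, `upper`, `is_reference`, `n`, `deaths`,
#'   `mortality`), `sample_mortality`, `threshold`, `flag` (`""`,
#'   `"no_association"`, or `"all_reference"`).
#' @export
derive_categories <- function(curve, records, tol = 0, alpha = 0.01,
                              min_run = 3) {
  stopifnot(inherits(curve, "vi_risk_curve"))
  x <- variable_values(records, curve$variable)
  y <- records$died_in_hospital
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  threshold <- curve$sample_mortality + tol
  res <- default_resolutions()[[curve$variable]]

  flag <- ""
  if (curve$lrt_p > alpha) {
    flag <- "no_association"
    prog <- rep(FALSE, length(curve$grid))
  } else {
    prog <- smooth_runs(curve$p_death > threshold, min_run)
    if (!any(prog)) flag <- "all_reference"
  }

  r <- rle(prog)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # Internal boundaries: interpolate the exact curve/threshold crossing
  # within the bracketing grid cell and snap to the nearest grid value, so
  # a crossing just past a grid point is not systematically pushed one
  # full resolution unit outward.
  boundary_at <- function(j) {
    p1 <- curve$p_death[j - 1L]
    p2 <- curve$p_death[j]
    if (is.na(p1) || (p1 - threshold) * (p2 - threshold) > 0 || p1 == p2) {
      return(curve$grid[j])
    }
    xc <- curve$grid[j - 1L] + res * (threshold - p1) / (p2 - p1)
    round(round(xc / res) * res, 10)
  }
  lower <- c(curve$grid[1], vapply(starts[-1], boundary_at, 0))
  upper <- c(lower[-1], curve$grid[length(curve$grid)] + res)
  cats <- data.frame(
    lower = round(lower, 10), upper = round(upper, 10),
    is_reference = !r$values
  )
  # The first/last categories absorb the trimmed tails so the categories
  # partition all observed records.
  in_cat <- function(i) {
    inside <- x >= cats$lower[i] & x < cats$upper[i]
    if (i == 1) inside <- inside | x < cats$lower[1]
    if (i == nrow(cats)) inside <- inside | x >= cats$upper[i]
    inside
  }
  cats$n <- vapply(seq_len(nrow(cats)), function(i) sum(in_cat(i)), 0L)
  cats$deaths <- vapply(seq_len(nrow(cats)), function(i) sum(y[in_cat(i)]), 0L)
  cats$mortality <- ifelse(cats$n > 0, cats$deaths / cats$n, NA_real_)

  structure(
    list(variable = curve$variable, categories = cats,
         sample_mortality = curve$sample_mortality,
         threshold = threshold, flag = flag),
    class = "vi_category_set"
  )
}

#' @export
print.vi_category_set <- function(x, ...) {
  cat(sprintf("<vi_category_set> %s (sample mortality %.1f%%%s)\n",
              x$variable, 100 * x$sample_mortality,
              if (nzchar(x$flag)) paste0(", flag: ", x$flag) else ""))
  cats <- x$categories
  for (i in seq_len(nrow(cats))) {
    cat(sprintf("  [%g, %g) %-10s n = %4d, mortality %s\n",
                cats$lower[i], cats$upper[i],
                if (cats$is_reference[i]) "reference" else "prognostic",
                cats$n[i],
                if (is.na(cats$mortality[i])) "-" else
                  sprintf("%.1f%%", 100 * cats$mortality[i])))
  }
  invisible(x)
}

#' Prognostic cutoffs of a category set
#'
#' The internal category boundaries, i.e. the cutoff values at which the
#' risk curve enters or leaves a prognostic range.
#'
#' @param category_set a `vi_category_set`.
#' @return numeric vector of boundary values (empty when the whole range is
#'   one category).
#' @export
category_cutoffs <- function(category_set) {
  cats <- category_set$categories
  if (nrow(cats) <= 1) return(numeric(0))
  cats$lower[-1]
}

#' Extract binary cutoffs into an index definition
#'
#' Turns per-variable category sets into a one-point-per-abnormality index:
#' each prognostic interval scores 1, reference ranges score 0, with
#' boundaries rounded to the variable's measurement resolution and extended
#' to the variable's full valid domain. Variables flagged flat or without
#' prognostic intervals are excluded. An optional GCS component (derived
#' categorically, see [derive_gcs_component()]) can be appended.
#'
#' @param category_sets list of `vi_category_set`s.
#' @param gcs_component optional `vi_component` for GCS.
#' @param name index name.
#' @return a `vi_index`, or `NULL` when no variable yields a prognostic
#'   interval.
#' @export
extract_cutoffs <- function(category_sets, gcs_component = NULL,
                            name = "derived") {
  resolutions <- default_resolutions()
  comps <- list()
  for (cs in category_sets) {
    cats <- cs$categories
    if (nzchar(cs$flag) || all(cats$is_reference)) next
    res <- resolutions[[cs$variable]]
    dom <- VARIABLE_DOMAINS[[cs$variable]]
    lower <- round(round(cats$lower / res) * res, 10)
    upper <- round(round(cats$upper / res) * res, 10)
    lower[1] <- dom[1]
    upper[nrow(cats)] <- dom[2]
    bands <- lapply(seq_len(nrow(cats)), function(i) {
      index_band(lower[i], upper[i], as.integer(!cats$is_reference[i]),
                 upper_closed = i == nrow(cats))
    })
    comps[[length(comps) + 1L]] <- index_component(cs$variable, bands)
  }
  if (!is.null(gcs_component)) comps[[length(comps) + 1L]] <- gcs_component
  if (length(comps) == 0) return(NULL)
  index_definition(name, comps)
}

#' Derive a binary GCS component from category mortality
#'
#' GCS is handled categorically (levels <=12, 13-14, 15), not splined.
#' Mortality in each level is compared with the sample average (plus `tol`);
#' the component scores 1 for all GCS at or below the highest prognostic
#' level (<=14 when level 13-14 is prognostic, <=12 when only that level
#' is), and is `NULL` when no level is prognostic.
#'
#' Like the splined vitals, GCS must first show evidence of association
#' with death: mortality below versus at the collapsed cutoff is compared
#' with Fisher's exact test and the component is dropped when `p > alpha`.
#'
#' @param records a `vi_cohort`.
#' @param tol tolerance above sample-average mortality (default 0).
#' @param alpha significance level for the association screen (default 0.01).
#' @return a `vi_component` or `NULL`.
#' @export
derive_gcs_component <- function(records, tol = 0, alpha = 0.01) {
  y <- records$died_in_hospital
  lev <- gcs_category(records$gcs)
  threshold <- mean(y) + tol
  mort <- vapply(levels(lev), function(l) {
    n <- sum(lev == l)
    if (n == 0) NA_real_ else mean(y[lev == l])
  }, 0)
  prog <- !is.na(mort) & mort > threshold
  cutoff <- if (prog[["13-14"]]) 14 else if (prog[["<=12"]]) 12 else NULL
  if (is.null(cutoff)) return(NULL)
  low <- records$gcs <= cutoff
  if (sum(low) == 0 || sum(!low) == 0) return(NULL)
  ft <- stats::fisher.test(table(low, y))
  if (ft$p.value > alpha) return(NULL)
  index_component("gcs", list(
    index_band(3, cutoff + 1, 1),
    index_band(cutoff + 1, 15, 0, upper_closed = TRUE)
  ))
}

#' Derive a prognostic index from a development cohort
#'
#' End-to-end derivation: fit a spline risk curve per continuous vital,
#' segment into reference/prognostic categories, extract cutoffs, and
#' append the categorical GCS component.
#'
#' @param records a `vi_cohort`.
#' @param variables continuous vitals to model (default map, temperature,
#'   resp_rate, pulse).
#' @param k knots per spline (default 7).
#' @param tol,alpha,min_run see [derive_categories()].
#' @param include_gcs append the categorical GCS component (default TRUE).
#' @param name name for the derived index.
#' @return list of class `vi_derivation`: `index` (a `vi_index`, or `NULL`
#'   when nothing is prognostic), `curves`, `category_sets`,
#'   `sample_mortality`.
#' @export
derive_index <- function(records,
                         variables = c("map", "temperature",
                                       "resp_rate", "pulse"),
                         k = 7, tol = 0, alpha = 0.01, min_run = 3,
                         include_gcs = TRUE, name = "derived") {
  curves <- lapply(variables, function(v) fit_risk_curve(records, v, k = k))
  names(curves) <- variables
  sets <- lapply(curves, derive_categories, records = records, tol = tol,
                 alpha = alpha, min_run = min_run)
  gcs_comp <- if (include_gcs) derive_gcs_component(records, tol = tol)
  structure(
    list(
      index = extract_cutoffs(sets, gcs_component = gcs_comp, name = name),
      curves = curves,
      category_sets = sets,
      sample_mortality = mean(records$died_in_hospital)
    ),
    class = "vi_derivation"
  )
}

#' @export
print.vi_derivation <- function(x, ...) {
  cat(sprintf("<vi_derivation> sample mortality %.1f%%\n",
              100 * x$sample_mortality))
  for (cs in x$category_sets) {
    cuts <- category_cutoffs(cs)
    cat(sprintf("  %-12s %s\n", cs$variable,
                if (nzchar(cs$flag)) cs$flag else
                  paste("cutoffs:", paste(cuts, collapse = ", "))))
  }
  if (is.null(x$index)) {
    cat("  no prognostic intervals; no index derived\n")
  } else {
    print(x$index)
  }
  invisible(x)
}
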