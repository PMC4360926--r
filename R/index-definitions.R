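# Prognostic index definitions: interval-band scoring tables for the
# reduced-segmentation index and the MEWS comparator, plus scoring of
# cohorts and per-score summaries.

# Valid value domains per scorable variable; bands of a component must
# cover its domain exactly.
VARIABLE_DOMAINS <- list(
  resp_rate = c(0, 200),
  pulse = c(0, 300),
  map = c(0, 400),
  sbp = c(0, 400),
  temperature = c(25, 45),
  gcs = c(3, 15)
)

#' Scoring band
#'
#' One interval-to-points mapping within an index component. Interval
#' endpoints carry explicit closures so printed clinical bands such as
#' "70 to 80" (closed) and "80 to 100" (left-open after severity
#' tie-breaking) can be represented exactly.
#'
#' @param lower,upper numeric interval endpoints, `lower <= upper`.
#' @param points non-negative integer points for values in the interval.
#' @param lower_closed,upper_closed whether each endpoint belongs to the
#'   interval.
#' @return list of class `vi_band`.
#' @export
index_band <- function(lower, upper, points,
                       lower_closed = TRUE, upper_closed = FALSE) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper,
            points >= 0, points == round(points))
  if (lower == upper && !(lower_closed && upper_closed)) {
    stopf("degenerate band [%s, %s] must be closed on both sides", lower, upper)
  }
  structure(
    list(lower = lower, upper = upper, points = as.integer(points),
         lower_closed = isTRUE(lower_closed),
         upper_closed = isTRUE(upper_closed)),
    class = "vi_band"
  )
}

band_contains <- function(band, x) {
  lo <- if (band$lower_closed) x >= band$lower else x > band$lower
  hi <- if (band$upper_closed) x <= band$upper else x < band$upper
  lo & hi
}

#' Index component
#'
#' An ordered set of scoring bands for one variable. The bands must be
#' pairwise disjoint and together cover the variable's valid domain, so
#' every value maps to exactly one points value.
#'
#' @param variable one of `resp_rate`, `pulse`, `map`, `temperature`,
#'   `gcs`, `sbp`.
#' @param bands list of [index_band()]s.
#' @param note optional free-text annotation (e.g. scoring anomalies).
#' @return list of class `vi_component`.
#' @export
index_component <- function(variable, bands, note = NULL) {
  if (!variable %in% names(VARIABLE_DOMAINS)) {
    stopf("unknown variable '%s'", variable)
  }
  stopifnot(length(bands) >= 1, all(vapply(bands, inherits, TRUE, "vi_band")))
  ord <- order(vapply(bands, `[[`, 0, "lower"),
               vapply(bands, `[[`, 0, "upper"))
  bands <- bands[ord]
  dom <- VARIABLE_DOMAINS[[variable]]
  b1 <- bands[[1]]
  bk <- bands[[length(bands)]]
  if (b1$lower > dom[1] || (!b1$lower_closed && b1$lower >= dom[1])) {
    stopf("%s bands do not cover the domain lower bound %s", variable, dom[1])
  }
  if (bk$upper < dom[2] || (!bk$upper_closed && bk$upper <= dom[2])) {
    stopf("%s bands do not cover the domain upper bound %s", variable, dom[2])
  }
  if (length(bands) > 1) {
    for (i in seq_len(length(bands) - 1)) {
      a <- bands[[i]]; b <- bands[[i + 1]]
      if (a$upper != b$lower || identical(a$upper_closed, b$lower_closed)) {
        stopf("%s bands must abut with exactly one side owning each boundary (at %s)",
              variable, a$upper)
      }
    }
  }
  structure(list(variable = variable, bands = bands, note = note),
            class = "vi_component")
}

component_points <- function(component, x) {
  pts <- rep(NA_integer_, length(x))
  for (band in component$bands) {
    hit <- !is.na(x) & band_contains(band, x)
    pts[hit] <- band$points
  }
  pts
}

#' Index definition
#'
#' A named collection of scored components; the total score of a record is
#' the sum of its component points.
#'
#' @param name index name.
#' @param components list of [index_component()]s.
#' @return list of class `vi_index` with fields `name`, `components`,
#'   `max_score`.
#' @export
index_definition <- function(name, components) {
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "vi_component")))
  vars <- vapply(components, `[[`, "", "variable")
  if (anyDuplicated(vars)) stopf("duplicate component variables")
  names(components) <- vars
  max_score <- sum(vapply(components, function(co) {
    max(vapply(co$bands, `[[`, 0L, "points"))
  }, 0L))
  structure(list(name = name, components = components,
                 max_score = as.integer(max_score)),
            class = "vi_index")
}

#' @export
print.vi_index <- function(x, ...) {
  cat(sprintf("<vi_index> %s (maximum score %d)\n", x$name, x$max_score))
  for (co in x$components) {
    scored <- Filter(function(b) b$points > 0, co$bands)
    desc <- vapply(scored, function(b) {
      sprintf("%s%s, %s%s -> %d",
              if (b$lower_closed) "[" else "(", b$lower,
              b$upper, if (b$upper_closed) "]" else ")", b$points)
    }, "")
    cat(sprintf("  %-12s %s\n", co$variable,
                if (length(desc) > 0) paste(desc, collapse = "; ") else "never scored"))
    if (!is.null(co$note)) cat(sprintf("               note: %s\n", co$note))
  }
  invisible(x)
}

#' The proposed reduced-segmentation prognostic index
#'
#' One point for each of: respiratory rate >= 30 cycles/minute; pulse
#' >= 100 beats/minute; MAP >= 110 or < 70 mmHg; temperature >= 38.6 or
#' < 35.6 degrees C; GCS <= 14 (altered mental state); 0 for all other
#' values. Maximum total score 5.
#'
#' @return a `vi_index`.
#' @export
proposed_index <- function() {
  index_definition("proposed", list(
    index_component("resp_rate", list(
      index_band(0, 30, 0),
      index_band(30, 200, 1, upper_closed = TRUE)
    )),
    index_component("pulse", list(
      index_band(0, 100, 0),
      index_band(100, 300, 1, upper_closed = TRUE)
    )),
    index_component("map", list(
      index_band(0, 70, 1),
      index_band(70, 110, 0),
      index_band(110, 400, 1, upper_closed = TRUE)
    )),
    index_component("temperature", list(
      index_band(25, 35.6, 1),
      index_band(35.6, 38.6, 0),
      index_band(38.6, 45, 1, upper_closed = TRUE)
    )),
    index_component("gcs", list(
      index_band(3, 15, 1),
      index_band(15, 15, 0, upper_closed = TRUE)
    ))
  ))
}

#' The Modified Early Warning Score (MEWS) comparator
#'
#' The MEWS banding used as comparator: 3 points for each of SBP < 70 mmHg,
#' pulse >= 130, respiratory rate >= 30, GCS <= 8; 2 points for SBP 70-80 or
#' >= 200, pulse 111-129, respiratory rate < 9 or 21-29, temperature < 35 or
#' >= 38.5, GCS 9-13; 1 point for SBP 80-100, pulse 40-50 or 101-110,
#' respiratory rate 16-20, GCS 14; 0 otherwise. Maximum total score 14.
#'
#' Where printed integer bands share a boundary (SBP 80, SBP 100), the
#' boundary is assigned to the higher-severity band. Pulse below 40 receives
#' no points in this enumeration and is annotated as an anomaly on the
#' component; no 1-point temperature band exists.
#'
#' @return a `vi_index`.
#' @export
mews_index <- function() {
  index_definition("MEWS", list(
    index_component("sbp", list(
      index_band(0, 70, 3),
      index_band(70, 80, 2, upper_closed = TRUE),
      index_band(80, 100, 1, lower_closed = FALSE, upper_closed = TRUE),
      index_band(100, 200, 0, lower_closed = FALSE),
      index_band(200, 400, 2, upper_closed = TRUE)
    )),
    index_component("pulse", list(
      index_band(0, 40, 0),
      index_band(40, 51, 1),
      index_band(51, 101, 0),
      index_band(101, 111, 1),
      index_band(111, 130, 2),
      index_band(130, 300, 3, upper_closed = TRUE)
    ), note = "pulse < 40 beats/minute is not assigned points"),
    index_component("resp_rate", list(
      index_band(0, 9, 2),
      index_band(9, 16, 0),
      index_band(16, 21, 1),
      index_band(21, 30, 2),
      index_band(30, 200, 3, upper_closed = TRUE)
    )),
    index_component("temperature", list(
      index_band(25, 35, 2),
      index_band(35, 38.5, 0),
      index_band(38.5, 45, 2, upper_closed = TRUE)
    )),
    index_component("gcs", list(
      index_band(3, 9, 3),
      index_band(9, 14, 2),
      index_band(14, 15, 1),
      index_band(15, 15, 0, upper_closed = TRUE)
    ))
  ))
}

#' Score a cohort with an index definition
#'
#' Computes the total index score for each record. MAP is always computed
#' on the fly from `sbp`/`dbp` via [mean_arterial_pressure()], never read
#' from a column, so scoring cannot disagree with the recorded pressures.
#'
#' @param records a `vi_cohort` or data.frame with the variables the
#'   definition references.
#' @param definition a `vi_index`, default [proposed_index()].
#' @return integer vector of total scores (one per record).
#' @export
score_cohort <- function(records, definition = proposed_index()) {
  stopifnot(inherits(definition, "vi_index"))
  total <- rep(0L, nrow(records))
  for (co in definition$components) {
    x <- if (co$variable == "map") {
      if (is.null(records$sbp) || is.null(records$dbp)) {
        stopf("index '%s' needs sbp and dbp to compute map", definition$name)
      }
      mean_arterial_pressure(records$sbp, records$dbp)
    } else {
      v <- records[[co$variable]]
      if (is.null(v)) {
        stopf("index '%s' references variable '%s' absent from the records",
              definition$name, co$variable)
      }
      v
    }
    pts <- component_points(co, x)
    if (anyNA(pts)) {
      bad <- which(is.na(pts))[1]
      id <- if (!is.null(records$patient_id)) records$patient_id[bad] else bad
      stopf("record %s: %s value %s is missing or outside the scorable domain",
            id, co$variable, x[bad])
    }
    total <- total + pts
  }
  total
}

#' Per-score patient and death counts
#'
#' Tabulates a cohort into one row per attained score with the number of
#' patients and in-hospital deaths, the shape of a per-score mortality
#' table.
#'
#' @param records a `vi_cohort` (needs `died_in_hospital`).
#' @param definition a `vi_index` used to score records.
#' @return data.frame of class `vi_score_dist` with columns `score`,
#'   `n_patients`, `n_deaths`, `mortality_pct`, plus attribute `label`.
#' @export
score_distribution <- function(records, definition = proposed_index()) {
  scores <- score_cohort(records, definition)
  score_distribution_from_scores(scores, records$died_in_hospital,
                                 label = cohort_label(records))
}

#' Build a score distribution from per-patient scores and outcomes
#'
#' @param score integer vector of index scores.
#' @param died logical vector of in-hospital death outcomes.
#' @param label cohort label.
#' @return a `vi_score_dist` (see [score_distribution()]).
#' @export
score_distribution_from_scores <- function(score, died, label = "cohort") {
  stopifnot(length(score) == length(died), !anyNA(score), !anyNA(died))
  lev <- sort(unique(score))
  n <- vapply(lev, function(s) sum(score == s), 0L)
  d <- vapply(lev, function(s) sum(died[score == s]), 0L)
  structure(
    data.frame(score = lev, n_patients = n, n_deaths = d,
               mortality_pct = 100 * d / n),
    label = label,
    class = c("vi_score_dist", "data.frame")
  )
}

#' @export
print.vi_score_dist <- function(x, ...) {
  cat(sprintf("<vi_score_dist> %s: %d patients, %d deaths\n",
              attr(x, "label") %||% "cohort",
              sum(x$n_patients), sum(x$n_deaths)))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Export an index definition as JSON
#'
#' @param definition a `vi_index`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_index_json <- function(definition, path) {
  stopifnot(inherits(definition, "vi_index"))
  doc <- list(
    name = definition$name,
    max_score = definition$max_score,
    components = lapply(unname(definition$components), function(co) {
      list(
        variable = co$variable,
        note = co$note,
        bands = lapply(co$bands, function(b) {
          list(lower = b$lower, upper = b$upper, points = b$points,
               lower_closed = b$lower_closed, upper_closed = b$upper_closed)
        })
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Import an index definition from JSON
#'
#' @param path path to a JSON document written by [write_index_json()].
#' @return a `vi_index`.
#' @export
read_index_json <- function(path) {
  doc <- jsonlite::read_json(path)
  comps <- lapply(doc$components, function(co) {
    bands <- lapply(co$bands, function(b) {
      index_band(b$lower, b$upper, b$points,
                 lower_closed = b$lower_closed, upper_closed = b$upper_closed)
    })
    index_component(co$variable, bands, note = co$note)
  })
  def <- index_definition(doc$name, comps)
  if (def$max_score != doc$max_score) {
    stopf("index JSON max_score %s disagrees with recomputed %d",
          doc$max_score, def$max_score)
  }
  def
}
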