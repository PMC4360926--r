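# Cohort data model: per-admission vital-sign records with outcome,
# CSV input/output, and record validation.

# Fixed column dictionary. Booleans are encoded 0/1 on disk; empty cells are
# missing and are allowed only for optional fields.
COHORT_REQUIRED <- c(
  "patient_id", "sbp", "dbp", "pulse", "resp_rate", "temperature",
  "gcs", "suspected_infection", "died_in_hospital"
)
COHORT_OPTIONAL <- c("age", "sex", "wbc", "platelets", "band_forms_pct")
COHORT_NUMERIC <- c(
  "age", "sbp", "dbp", "pulse", "resp_rate", "temperature", "gcs",
  "wbc", "platelets", "band_forms_pct"
)
COHORT_LOGICAL <- c("suspected_infection", "died_in_hospital")

#' Column dictionary for cohort CSV files
#'
#' @return A data.frame with one row per recognised column: name, type,
#'   whether the column is required, and units.
#' @export
cohort_columns <- function() {
  data.frame(
    name = c(COHORT_REQUIRED, COHORT_OPTIONAL),
    type = c(
      "character", rep("numeric", 6), rep("logical", 2),
      "numeric", "character", rep("numeric", 3)
    ),
    required = c(rep(TRUE, length(COHORT_REQUIRED)),
                 rep(FALSE, length(COHORT_OPTIONAL))),
    units = c(
      "", "mmHg", "mmHg", "beats/minute", "cycles/minute",
      "degrees Celsius (axillary)", "Glasgow coma score, 3-15",
      "0/1", "0/1",
      "years", "male/female", "x10^3 cells/cc", "x10^3 cells/cc", "percent"
    ),
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort from a data frame of patient records
#'
#' A cohort is a validated data.frame of one-admission-per-row vital sign
#' records with an in-hospital death outcome. Optional columns absent from
#' `records` are added as all-missing.
#'
#' @param records data.frame with (at least) the required columns of
#'   [cohort_columns()].
#' @param label cohort label, e.g. `"development"` or `"validation"`.
#' @param strict if `TRUE` (default) any invalid record is an error; if
#'   `FALSE` invalid records are dropped and reported in the
#'   `"drop_report"` attribute.
#' @return An object of class `vi_cohort` (a data.frame).
#' @export
cohort <- function(records, label = "cohort", strict = TRUE) {
  if (!is.data.frame(records)) stopf("`records` must be a data.frame")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_REQUIRED, names(records))
  if (length(missing_cols) > 0) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(COHORT_OPTIONAL, names(records))) {
    records[[col]] <- if (col == "sex") NA_character_ else NA_real_
  }
  records <- records[, c(COHORT_REQUIRED, COHORT_OPTIONAL)]
  records$patient_id <- as.character(records$patient_id)
  for (col in COHORT_NUMERIC) records[[col]] <- as.numeric(records[[col]])
  for (col in COHORT_LOGICAL) {
    v <- records[[col]]
    if (!is.logical(v)) v <- as.logical(as.numeric(v))
    records[[col]] <- v
  }
  viol <- validate_records(records)
  if (nrow(viol) > 0) {
    if (strict) {
      stopf(
        "invalid record(s):\n%s",
        paste(sprintf("  row %d (%s): %s", viol$row, viol$patient_id,
                      viol$problem), collapse = "\n")
      )
    }
    records <- records[-unique(viol$row), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(
    records,
    label = label,
    drop_report = if (nrow(viol) > 0) viol else NULL,
    class = c("vi_cohort", "data.frame")
  )
}

#' Validate cohort records against the record invariants
#'
#' Checks every record against the domain invariants (positive pressures with
#' dbp <= sbp, positive pulse and respiratory rate, temperature within 25-45
#' degrees C, GCS an integer in 3-15, non-negative optional labs, 0/1
#' outcome and infection flags, unique non-empty patient ids). Validation is
#' total: every record either passes or yields at least one classified
#' violation row.
#'
#' @param records data.frame with the cohort columns.
#' @return data.frame with columns `row`, `patient_id`, `field`, `problem`
#'   (zero rows when all records are valid).
#' @export
validate_records <- function(records) {
  viol <- list()
  add <- function(rows, field, problem) {
    if (length(rows) > 0) {
      viol[[length(viol) + 1L]] <<- data.frame(
        row = rows,
        patient_id = as.character(records$patient_id[rows]),
        field = field, problem = problem, stringsAsFactors = FALSE
      )
    }
  }
  n <- nrow(records)
  idx <- seq_len(n)

  for (col in COHORT_REQUIRED) {
    bad <- idx[is.na(records[[col]]) |
                 (col == "patient_id" & !nzchar(records[[col]]))]
    add(bad, col, sprintf("required field %s is missing", col))
  }
  dup <- idx[duplicated(records$patient_id) & !is.na(records$patient_id)]
  add(dup, "patient_id", "duplicate patient_id")

  ok <- function(cond) idx[!is.na(cond) & !cond]
  add(ok(records$sbp > 0), "sbp", "sbp must be > 0")
  add(ok(records$dbp > 0), "dbp", "dbp must be > 0")
  add(ok(records$dbp <= records$sbp), "dbp", "dbp must be <= sbp")
  add(ok(records$pulse > 0), "pulse", "pulse must be > 0")
  add(ok(records$resp_rate > 0), "resp_rate", "resp_rate must be > 0")
  add(ok(records$temperature >= 25 & records$temperature <= 45),
      "temperature", "temperature must be in [25, 45]")
  add(ok(records$gcs >= 3 & records$gcs <= 15 &
           records$gcs == round(records$gcs)),
      "gcs", "gcs must be an integer in [3, 15]")
  add(ok(records$age >= 0), "age", "age must be >= 0")
  add(ok(is.na(records$sex) | records$sex %in% c("male", "female")),
      "sex", "sex must be male or female")
  for (col in c("wbc", "platelets", "band_forms_pct")) {
    add(ok(records[[col]] >= 0), col, sprintf("%s must be >= 0", col))
  }
  add(ok(records$band_forms_pct <= 100), "band_forms_pct",
      "band_forms_pct must be <= 100")

  if (length(viol) == 0) {
    return(data.frame(row = integer(), patient_id = character(),
                      field = character(), problem = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  out <- out[order(out$row), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.vi_cohort <- function(x, ...) {
  cat(sprintf("<vi_cohort> '%s': %d records, %d deaths (%.1f%%)\n",
              cohort_label(x), nrow(x), sum(x$died_in_hospital),
              100 * mean(x$died_in_hospital)))
  dropped <- attr(x, "drop_report")
  if (!is.null(dropped)) {
    cat(sprintf("  (%d invalid record(s) dropped on construction)\n",
                length(unique(dropped$row))))
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Cohort label accessor
#' @param x a `vi_cohort`.
#' @return character label.
#' @export
cohort_label <- function(x) attr(x, "label") %||% "cohort"

#' Read a cohort from a CSV file
#'
#' Parses a cohort CSV (RFC-4180, UTF-8, header row required; see
#' [cohort_columns()] for the column dictionary, matched case-insensitively).
#' Empty cells are missing values and are only allowed for optional fields.
#'
#' @param path path to the CSV file.
#' @param strict if `TRUE` any invalid record aborts with an error naming the
#'   row; if `FALSE` invalid records are dropped, with the drop report
#'   available as `attr(x, "drop_report")`.
#' @param label cohort label; defaults to the file name.
#' @return A `vi_cohort`.
#' @export
read_cohort <- function(path, strict = TRUE, label = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(COHORT_REQUIRED, names(raw))
  if (length(missing_cols) > 0) {
    stopf("cohort file %s is missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(raw), c(COHORT_REQUIRED, COHORT_OPTIONAL))
  if (length(unknown) > 0) {
    warnf("ignoring unrecognised column(s): %s", paste(unknown, collapse = ", "))
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  for (col in setdiff(COHORT_OPTIONAL, names(raw))) raw[[col]] <- NA_character_
  raw[] <- lapply(raw, function(v) {
    v <- trimws(v)
    v[!nzchar(v)] <- NA_character_
    v
  })
  # Numeric parsing with row-level diagnostics.
  for (col in COHORT_NUMERIC) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stopf("unparseable numeric value '%s' in column %s, row %d of %s",
            raw[[col]][bad[1]], col, bad[1], path)
    }
    raw[[col]] <- parsed
  }
  for (col in COHORT_LOGICAL) {
    v <- tolower(raw[[col]])
    parsed <- rep(NA, length(v))
    parsed[v %in% c("1", "true", "t", "yes")] <- TRUE
    parsed[v %in% c("0", "false", "f", "no")] <- FALSE
    bad <- which(is.na(parsed) & !is.na(v))
    if (length(bad) > 0) {
      stopf("unparseable boolean value '%s' in column %s, row %d of %s",
            raw[[col]][bad[1]], col, bad[1], path)
    }
    raw[[col]] <- parsed
  }
  cohort(raw, label = label %||% sub("\\.csv$", "", basename(path)),
         strict = strict)
}

#' Write a cohort to a CSV file
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, path))`
#' reproduces `x` field for field. Booleans are written as 0/1 and missing
#' values as empty cells.
#'
#' @param x a `vi_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "vi_cohort"))
  out <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in COHORT_LOGICAL) out[[col]] <- as.integer(out[[col]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("could not write cohort to %s: %s", path,
                         conditionMessage(ok))
  invisible(path)
}
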