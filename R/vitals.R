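# Derived clinical quantities: mean arterial pressure, SIRS criteria,
# sepsis / severe sepsis classification, and GCS categories.

#' Mean arterial pressure
#'
#' MAP is the weighted average of systolic and diastolic pressure,
#' (SBP + 2 DBP) / 3, reflecting that diastole occupies roughly two thirds
#' of the cardiac cycle.
#'
#' @param sbp systolic blood pressure, mmHg (vector).
#' @param dbp diastolic blood pressure, mmHg (vector).
#' @return MAP in mmHg; always within `[dbp, sbp]`.
#' @export
#' @examples
#' mean_arterial_pressure(100, 60)  # 73.33
mean_arterial_pressure <- function(sbp, dbp) {
  bad <- which(!is.na(sbp) & !is.na(dbp) & (dbp > sbp | dbp <= 0 | sbp <= 0))
  if (length(bad) > 0) {
    stopf("invalid pressures at position %d: need 0 < dbp <= sbp (sbp=%s, dbp=%s)",
          bad[1], sbp[bad[1]], dbp[bad[1]])
  }
  (sbp + 2 * dbp) / 3
}

#' Count satisfied SIRS criteria
#'
#' The four systemic inflammatory response syndrome criteria, evaluated at
#' admission: pulse >= 90 beats/minute; respiratory rate >= 20 cycles/minute;
#' temperature >= 38 or <= 36 degrees C; and white cell count >= 12 or < 4
#' (x10^3 cells/cc) or > 10% band forms. The white-cell criterion counts if
#' any of its three sub-conditions holds; when both wbc and band forms are
#' missing it contributes 0 and the record is flagged in the
#' `"wbc_unassessed"` attribute.
#'
#' @param records a `vi_cohort` or data.frame with columns `pulse`,
#'   `resp_rate`, `temperature`, and optionally `wbc`, `band_forms_pct`.
#' @return integer vector of counts in 0-4 with attribute `wbc_unassessed`
#'   (logical vector).
#' @export
sirs_count <- function(records) {
  pulse_crit <- records$pulse >= 90
  resp_crit <- records$resp_rate >= 20
  temp_crit <- records$temperature >= 38 | records$temperature <= 36
  wbc <- records$wbc %||% rep(NA_real_, nrow(records))
  bands <- records$band_forms_pct %||% rep(NA_real_, nrow(records))
  wbc_crit <- (!is.na(wbc) & (wbc >= 12 | wbc < 4)) |
    (!is.na(bands) & bands > 10)
  unassessed <- is.na(wbc) & is.na(bands)
  n <- as.integer(pulse_crit) + as.integer(resp_crit) +
    as.integer(temp_crit) + as.integer(wbc_crit)
  structure(n, wbc_unassessed = unassessed)
}

#' Classify sepsis and severe sepsis
#'
#' Sepsis is suspected infection plus two or more SIRS criteria. Severe
#' sepsis is sepsis plus at least one organ dysfunction: GCS < 15,
#' SBP < 90 mmHg, or platelets < 100 (x10^3 cells/cc). Organ-dysfunction
#' flags report which conditions held regardless of sepsis status; the
#' severe-sepsis flag additionally requires sepsis.
#'
#' @param records a `vi_cohort` or data.frame with the cohort columns.
#' @return data.frame with `patient_id`, `sirs_count`, `has_sepsis`,
#'   `has_severe_sepsis`, `low_gcs`, `low_sbp`, `low_platelets`.
#' @export
classify_sepsis <- function(records) {
  n_sirs <- sirs_count(records)
  has_sepsis <- records$suspected_infection & n_sirs >= 2
  low_gcs <- records$gcs < 15
  low_sbp <- records$sbp < 90
  low_platelets <- !is.na(records$platelets) & records$platelets < 100
  data.frame(
    patient_id = records$patient_id,
    sirs_count = as.integer(n_sirs),
    has_sepsis = has_sepsis,
    has_severe_sepsis = has_sepsis & (low_gcs | low_sbp | low_platelets),
    low_gcs = low_gcs,
    low_sbp = low_sbp,
    low_platelets = low_platelets,
    stringsAsFactors = FALSE
  )
}

#' Categorize Glasgow coma scores
#'
#' Partitions GCS into the three analysis levels `<=12`, `13-14`, `15`
#' (exhaustive and mutually exclusive over the valid range 3-15).
#'
#' @param gcs integer vector of Glasgow coma scores.
#' @return factor with levels `"<=12"`, `"13-14"`, `"15"`.
#' @export
gcs_category <- function(gcs) {
  bad <- which(!is.na(gcs) & (gcs < 3 | gcs > 15 | gcs != round(gcs)))
  if (length(bad) > 0) {
    stopf("gcs out of range at position %d: %s (must be integer in [3, 15])",
          bad[1], gcs[bad[1]])
  }
  cut(gcs, breaks = c(2.5, 12.5, 14.5, 15.5),
      labels = c("<=12", "13-14", "15"))
}
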