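# Patient-level cohort handling: PSA density, PSAD risk bands, disease
# status, validation and CSV import/export.

#' PSAD risk-band boundaries
#'
#' Upper boundaries (ng/mL\eqn{^2}) separating the four PSA-density risk
#' bands. Bands are half-open on the right: `low` is \[0, 0.10), ...,
#' `very_high` is \[0.20, Inf). The half-open convention at 0.20 follows the
#' "\eqn{\ge} 0.20" grouping used in prevalence cross-tabulations; change
#' this single constant to move the convention.
#'
#' @format Named numeric vector of length 3.
#' @export
psad_band_breaks <- c(low = 0.10, intermediate = 0.15, high = 0.20)

#' Ordered PSAD band levels, lowest risk first
#' @export
psad_band_levels <- c("low", "intermediate", "high", "very_high")

#' Disease-status levels
#'
#' `cspca` = clinically significant prostate cancer (ISUP grade group >= 2),
#' `ipca` = insignificant cancer (ISUP 1), `negative` = benign biopsy or no
#' biopsy (presumed negative under follow-up).
#' @export
disease_status_levels <- c("cspca", "ipca", "negative")

#' Compute PSA density
#'
#' PSA density (PSAD) is serum PSA divided by prostate volume, in
#' ng/mL\eqn{^2}.
#'
#' @param psa Serum PSA in ng/mL; positive.
#' @param volume Prostate volume in mL; positive.
#' @return PSAD in ng/mL^2 (`psa / volume`), vectorised.
#' @examples
#' compute_psad(10, 50)    # 0.20
#' compute_psad(6.31, 54.7)
#' @export
compute_psad <- function(psa, volume) {
  if (length(psa) == 0 || length(volume) == 0) {
    rlang::abort("`psa` and `volume` must be non-empty.", class = "psadpathways_validation_error")
  }
  if (any(!is.finite(psa)) || any(psa <= 0)) {
    rlang::abort("`psa` must be finite and positive (ng/mL).",
                 class = "psadpathways_validation_error")
  }
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    rlang::abort("`volume` must be finite and positive (mL).",
                 class = "psadpathways_validation_error")
  }
  psa / volume
}

#' Assign PSAD risk bands
#'
#' Maps PSAD values to the four risk bands `low` (< 0.10), `intermediate`
#' (0.10-0.15), `high` (0.15-0.20) and `very_high` (>= 0.20), using
#' half-open intervals \[a, b) defined by [psad_band_breaks].
#'
#' @param psad PSAD values in ng/mL^2; positive.
#' @return Ordered factor with levels [psad_band_levels].
#' @examples
#' assign_psad_band(c(0.05, 0.10, 0.15, 0.20))
#' @export
assign_psad_band <- function(psad) {
  if (any(!is.finite(psad)) || any(psad <= 0)) {
    rlang::abort("`psad` must be finite and positive (ng/mL^2).",
                 class = "psadpathways_validation_error")
  }
  cut(psad,
      breaks = c(0, unname(psad_band_breaks), Inf),
      labels = psad_band_levels,
      right = FALSE, ordered_result = TRUE)
}

#' Classify ground-truth disease status
#'
#' ISUP grade group >= 2 (Gleason >= 3+4) is clinically significant cancer
#' (`cspca`); ISUP 1 (Gleason 3+3) is insignificant cancer (`ipca`); a
#' benign biopsy (grade group 0) or no biopsy is `negative` — men without a
#' biopsy are presumed negative under follow-up.
#'
#' @param cohort A cohort tibble (see [validate_cohort]), or a data frame
#'   with at least `biopsied` and `isup_grade_group` columns.
#' @return Factor with levels [disease_status_levels], one per row.
#' @export
disease_status <- function(cohort) {
  biopsied <- cohort$biopsied
  isup <- cohort$isup_grade_group
  if (any(biopsied & is.na(isup))) {
    bad <- which(biopsied & is.na(isup))[1]
    rlang::abort(
      sprintf("Row %d: biopsied patient has no ISUP grade group.", bad),
      class = "psadpathways_validation_error")
  }
  status <- rep("negative", nrow(cohort))
  status[biopsied & !is.na(isup) & isup >= 2] <- "cspca"
  status[biopsied & !is.na(isup) & isup == 1] <- "ipca"
  factor(status, levels = disease_status_levels)
}

#' Group PI-RADS scores as 1-2 / 3 / 4-5
#'
#' The grouping used for prevalence cross-tabulation: negative (1-2),
#' equivocal (3) and positive (4-5) MRI.
#'
#' @param pirads Integer PI-RADS scores in 1..5.
#' @return Ordered factor with levels `"1-2" < "3" < "4-5"`.
#' @export
pirads_group <- function(pirads) {
  cut(pirads, breaks = c(0.5, 2.5, 3.5, 5.5), labels = c("1-2", "3", "4-5"),
      ordered_result = TRUE)
}

# Canonical cohort CSV column order.
cohort_columns <- c("patient_id", "age", "psa", "prostate_volume", "psad",
                    "pirads", "biopsied", "isup_grade_group",
                    "followup_months", "study_date")

# Relative tolerance for agreement between a supplied psad column and
# psa / prostate_volume.
psad_consistency_rtol <- 1e-6

#' Validate a patient-level cohort
#'
#' Checks a cohort tibble against the schema: unique `patient_id`, PI-RADS
#' in 1..5, positive PSAD (supplied or derived from `psa / prostate_volume`;
#' if both routes are available they must agree to a relative 1e-6), ISUP
#' grade group in 0..5 and only present for biopsied patients, non-negative
#' follow-up. Missing `psad` is filled from `psa / prostate_volume`.
#'
#' @param cohort A data frame with at least `patient_id`, `pirads`,
#'   `biopsied` and a PSAD route (`psad`, or `psa` + `prostate_volume`).
#' @param strict_biopsied_truth If `TRUE`, non-biopsied patients are dropped
#'   rather than presumed negative. Default `FALSE` (the presumed-negative
#'   convention).
#' @return The validated cohort as a tibble with canonical columns, errors
#'   (class `psadpathways_validation_error`) naming the offending row and
#'   column otherwise.
#' @export
validate_cohort <- function(cohort, strict_biopsied_truth = FALSE) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) {
    rlang::abort("Cohort is empty; analytic operations need >= 1 patient.",
                 class = "psadpathways_validation_error")
  }
  fail <- function(row, col, msg) {
    rlang::abort(sprintf("Cohort row %s, column `%s`: %s", row, col, msg),
                 class = "psadpathways_validation_error")
  }
  need <- c("patient_id", "pirads", "biopsied")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    rlang::abort(sprintf("Cohort is missing mandatory column(s): %s.",
                         paste0("`", miss, "`", collapse = ", ")),
                 class = "psadpathways_schema_error")
  }
  if (!("psad" %in% names(cohort)) &&
      !all(c("psa", "prostate_volume") %in% names(cohort))) {
    rlang::abort(
      "Cohort needs a `psad` column or both `psa` and `prostate_volume`.",
      class = "psadpathways_schema_error")
  }
  for (col in setdiff(cohort_columns, names(cohort))) {
    cohort[[col]] <- switch(col,
      patient_id = , study_date = NA_character_,
      biopsied = NA,
      pirads = , isup_grade_group = , age = NA_integer_,
      NA_real_)
  }
  cohort <- cohort[cohort_columns]

  dup <- cohort$patient_id[duplicated(cohort$patient_id)]
  if (length(dup) > 0) {
    fail(which(cohort$patient_id == dup[1])[2], "patient_id",
         sprintf("duplicate id '%s'.", dup[1]))
  }
  if (anyNA(cohort$patient_id)) {
    fail(which(is.na(cohort$patient_id))[1], "patient_id", "missing id.")
  }
  bad <- which(is.na(cohort$pirads) | !(cohort$pirads %in% 1:5))
  if (length(bad) > 0) fail(bad[1], "pirads", "PI-RADS score must be in 1..5.")
  bad <- which(is.na(cohort$biopsied))
  if (length(bad) > 0) fail(bad[1], "biopsied", "must be true or false.")

  derived <- ifelse(!is.na(cohort$psa) & !is.na(cohort$prostate_volume),
                    cohort$psa / cohort$prostate_volume, NA_real_)
  bad <- which(!is.na(cohort$psa) & cohort$psa <= 0)
  if (length(bad) > 0) fail(bad[1], "psa", "must be positive.")
  bad <- which(!is.na(cohort$prostate_volume) & cohort$prostate_volume <= 0)
  if (length(bad) > 0) fail(bad[1], "prostate_volume", "must be positive.")
  # Supplied psad wins; derived fills gaps; disagreement beyond tolerance errors.
  bad <- which(!is.na(cohort$psad) & !is.na(derived) &
                 abs(cohort$psad - derived) > psad_consistency_rtol * cohort$psad)
  if (length(bad) > 0) {
    fail(bad[1], "psad",
         sprintf("inconsistent with psa/prostate_volume (%.6g vs %.6g).",
                 cohort$psad[bad[1]], derived[bad[1]]))
  }
  cohort$psad <- ifelse(is.na(cohort$psad), derived, cohort$psad)
  bad <- which(is.na(cohort$psad) | cohort$psad <= 0)
  if (length(bad) > 0) fail(bad[1], "psad", "missing or non-positive PSAD.")

  bad <- which(!is.na(cohort$isup_grade_group) &
                 !(cohort$isup_grade_group %in% 0:5))
  if (length(bad) > 0) fail(bad[1], "isup_grade_group", "must be in 0..5.")
  bad <- which(!is.na(cohort$isup_grade_group) & !cohort$biopsied)
  if (length(bad) > 0) {
    fail(bad[1], "isup_grade_group", "present for a non-biopsied patient.")
  }
  bad <- which(cohort$biopsied & is.na(cohort$isup_grade_group))
  if (length(bad) > 0) {
    fail(bad[1], "isup_grade_group", "missing for a biopsied patient.")
  }
  bad <- which(!is.na(cohort$followup_months) & cohort$followup_months < 0)
  if (length(bad) > 0) fail(bad[1], "followup_months", "must be non-negative.")

  if (strict_biopsied_truth) cohort <- cohort[cohort$biopsied, ]
  cohort
}

#' Read a patient-level cohort from CSV
#'
#' Expects the documented schema: columns `patient_id, age, psa,
#' prostate_volume, psad, pirads, biopsied, isup_grade_group,
#' followup_months, study_date` (header mandatory, UTF-8, empty string =
#' missing, booleans `true`/`false`). `psad` may be omitted when `psa` and
#' `prostate_volume` are present.
#'
#' @param path Path to a CSV file.
#' @param strict_biopsied_truth Passed to [validate_cohort].
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path, strict_biopsied_truth = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Cohort file '%s' does not exist.", path),
                 class = "psadpathways_schema_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  types <- list(
    patient_id = readr::col_character(), age = readr::col_integer(),
    psa = readr::col_double(), prostate_volume = readr::col_double(),
    psad = readr::col_double(), pirads = readr::col_integer(),
    biopsied = readr::col_logical(),
    isup_grade_group = readr::col_integer(),
    followup_months = readr::col_double(),
    study_date = readr::col_character())
  # parsing problems surface as an explicit schema error below, not a warning
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = do.call(readr::cols_only,
                                              types[intersect(names(types), header)]),
                    na = c("", "NA"), progress = FALSE))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    rlang::abort(sprintf(
      "Unparsable value in '%s' at row %d, column %d (expected %s).",
      path, prob$row[1], prob$col[1], prob$expected[1]),
      class = "psadpathways_schema_error")
  }
  validate_cohort(raw, strict_biopsied_truth = strict_biopsied_truth)
}

#' Write a cohort to CSV
#'
#' Writes the documented schema (booleans as `true`/`false`, missing values
#' as empty strings). `write_cohort_csv()` then [read_cohort_csv()] round-trips
#' all fields (reals to full double precision).
#'
#' @param cohort A cohort tibble (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort
  out$biopsied <- ifelse(out$biopsied, "true", "false")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
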