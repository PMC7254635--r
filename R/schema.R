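#' Cohort schema
#'
#' The cohort table is one row per patient. Clustering uses seven annual
#' utilisation counts; the remaining columns are profiling attributes and may
#' be absent (summaries then skip them) or missing per record (excluded
#' pairwise per summary).
#'
#' @section Required columns:
#' `patient_id` plus the seven utilisation counts returned by
#' [utilisation_settings()]: non-elective and elective inpatient admissions,
#' outpatient first and follow-up attendances, GP practice visits, count of
#' distinct drugs prescribed in the year, and A&E attendances. All are
#' non-negative integers per patient-year.
#'
#' @section Optional profiling columns:
#' `age` (years), `sex` (`"F"`/`"M"`), `deprived_q12` (lives in national
#' deprivation quintile 1 or 2), `smoker`, `risk_score` (probability of
#' emergency admission within 12 months, in `[0, 1]`), `ltc_count` (total
#' long-term conditions; carried as its own column because it may count
#' conditions beyond the named flags), `frail_mod_severe`, `cost_gbp`
#' (annual cost), `bed_days_elective`, `bed_days_nonelective`,
#' `bed_days_maternity`, one `ltc_*` flag per condition in
#' [ltc_conditions()], and `true_segment` (generator truth label, never a
#' clustering input). Booleans are encoded 0/1 on disk and logical in R.
#'
#' @return `utilisation_settings()` and `ltc_conditions()` return character
#'   vectors of column names.
#' @examples
#' utilisation_settings()
#' @name cohort-schema
NULL

#' @rdname cohort-schema
#' @export
utilisation_settings <- function() {
  c("nonelective_adm", "elective_adm", "op_first", "op_followup",
    "gp_visits", "distinct_drugs", "ae_attendances")
}

#' @rdname cohort-schema
#' @export
ltc_conditions <- function() {
  c("armd", "arthritis", "asthma", "bipolar", "chf", "copd", "crf",
    "depression", "diabetes", "glaucoma", "hypertension", "hyperthyroidism",
    "ihd", "low_back_pain", "osteoporosis", "parkinsons", "schizophrenia",
    "seizure")
}

ltc_flag_cols <- function() paste0("ltc_", ltc_conditions())

bool_cols <- function() {
  c("deprived_q12", "smoker", "frail_mod_severe", ltc_flag_cols())
}

required_cols <- function() c("patient_id", utilisation_settings())

#' Validate a cohort table
#'
#' Checks the schema and the per-record invariants on the seven utilisation
#' variables: present, non-negative, integer-valued. In strict mode any
#' violation is fatal; otherwise offending records are dropped and the count
#' of drops is reported and attached as the `"dropped"` attribute.
#'
#' @param cohort A data frame with at least `patient_id` and the seven
#'   utilisation columns.
#' @param strict Logical; if `TRUE` (default) any missing or non-integer or
#'   negative utilisation value is an error.
#' @return A validated tibble (invisibly classed as before), with attribute
#'   `dropped` giving the number of records removed in non-strict mode.
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame.")
  missing_cols <- setdiff(required_cols(), names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cohort <- tibble::as_tibble(cohort)
  if (anyDuplicated(cohort$patient_id)) {
    abort("`patient_id` values must be unique.")
  }
  util <- utilisation_settings()
  if (nrow(cohort) == 0) {
    # header-only tables carry no type information
    for (v in util) cohort[[v]] <- as.integer(cohort[[v]])
    for (v in intersect(bool_cols(), names(cohort))) {
      cohort[[v]] <- as.logical(cohort[[v]])
    }
  }
  bad <- rep(FALSE, nrow(cohort))
  for (v in util) {
    x <- cohort[[v]]
    if (!is.numeric(x)) {
      if (strict) abort(paste0("Utilisation column `", v, "` is not numeric."))
      bad <- bad | TRUE
      next
    }
    x_na <- is.na(x)
    x_neg <- !x_na & x < 0
    x_frac <- !x_na & !x_neg & abs(x - round(x)) > 1e-8
    if (strict) {
      if (any(x_na)) {
        abort(paste0("Missing value in utilisation column `", v,
                     "` at row ", which(x_na)[1], "."))
      }
      if (any(x_neg)) {
        abort(paste0("Negative count in utilisation column `", v,
                     "` at row ", which(x_neg)[1], "."))
      }
      if (any(x_frac)) {
        abort(paste0("Non-integer count in utilisation column `", v,
                     "` at row ", which(x_frac)[1], "."))
      }
    }
    bad <- bad | x_na | x_neg | x_frac
  }
  dropped <- sum(bad)
  if (!strict && dropped > 0) {
    inform(paste0("Dropped ", dropped,
                  " record(s) with invalid utilisation values."))
    cohort <- cohort[!bad, , drop = FALSE]
  }
  if ("risk_score" %in% names(cohort)) {
    rs <- cohort$risk_score
    out_of_range <- !is.na(rs) & (rs < 0 | rs > 1)
    if (any(out_of_range)) {
      abort(paste0("`risk_score` outside [0, 1] at row ",
                   which(out_of_range)[1], "."))
    }
  }
  for (v in intersect(bool_cols(), names(cohort))) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      if (any(!is.na(x) & !x %in% c(0, 1))) {
        abort(paste0("Boolean column `", v, "` must be coded 0/1."))
      }
      cohort[[v]] <- as.logical(x)
    }
  }
  if (!strict) attr(cohort, "dropped") <- dropped
  cohort
}
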