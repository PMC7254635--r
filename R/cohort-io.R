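#' Read a cohort table from CSV
#'
#' Reads a UTF-8 CSV with a header row, one patient per line, booleans coded
#' 0/1, and validates it against the cohort schema (see [cohort-schema]).
#' Column aliases can be supplied to map non-standard headers onto the schema
#' names.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default), any missing, negative or non-integer
#'   utilisation value aborts; if `FALSE`, offending records are dropped and
#'   the number dropped is reported and attached as attribute `"dropped"`.
#' @param aliases Optional named character vector mapping schema names to the
#'   headers used in the file, e.g. `c(gp_visits = "GP_visit_count")`.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, strict = TRUE, aliases = NULL) {
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(aliases)) {
    for (std in names(aliases)) {
      if (aliases[[std]] %in% names(df)) {
        names(df)[names(df) == aliases[[std]]] <- std
      }
    }
  }
  validate_cohort(df, strict = strict)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: booleans are written 0/1 and the round trip
#' reproduces the cohort field for field.
#'
#' @param cohort A validated cohort data frame.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort, strict = TRUE)
  out <- cohort
  for (v in intersect(bool_cols(), names(out))) {
    out[[v]] <- as.integer(out[[v]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(cohort)
}
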