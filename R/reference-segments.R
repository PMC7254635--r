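# Built-in ten-segment reference profile of a deprived GP-registered
# population (79,607 patients). These printed per-segment
# summaries parameterise the default synthetic-cohort generator and supply the
# worked examples for the need/complexity rule and the share arithmetic.

#' Reference segment profiles
#'
#' Per-segment summary statistics for the ten utilisation-based segments of a
#' real GP-registered population of 79,607 patients that this package's
#' defaults emulate: population counts, mean (SD) annual utilisation in the
#' seven care settings, demographic/risk attributes, long-term-condition
#' prevalences, frailty, bed days, published costs and the published
#' need/complexity characterisation of each segment.
#'
#' @return A tibble with one row per segment (`segment` 1-10) and columns:
#'   `n_people`; `util_<setting>` means; `age_mean`, `age_sd`; `deprived_pct`,
#'   `smoker_pct`; `risk_mean`, `risk_sd`; `ltc_count_mean`;
#'   `ltc_<condition>_pct` prevalences; `frail_pct`; `bed_days_*`;
#'   `total_cost_m` (GBP millions), `cost_per_head_gbp`, `cost_ratio`
#'   (published cost-to-population ratio); `characterisation` (published
#'   high/low need-complexity label).
#' @examples
#' ref <- segment_reference_profiles()
#' sum(ref$n_people)
#' @export
segment_reference_profiles <- function() {
  util <- utilisation_settings()
  m <- rbind(
    c(0.01, 0.00, 0.00, 0.14, 0.11, 1.78, 0.00),
    c(0.17, 1.22, 0.87, 2.02, 1.34, 8.11, 0.48),
    c(1.27, 0.03, 0.39, 1.17, 1.30, 6.65, 1.52),
    c(3.27, 0.36, 1.79, 4.22, 4.94, 15.90, 5.13),
    c(0.02, 0.00, 1.23, 1.17, 0.93, 4.31, 0.28),
    c(0.34, 0.14, 1.89, 3.66, 4.60, 15.00, 1.13),
    c(0.35, 0.10, 1.26, 20.53, 1.55, 8.28, 0.69),
    c(0.02, 0.00, 0.17, 0.79, 0.71, 12.35, 0.14),
    c(1.25, 0.14, 0.92, 2.26, 7.55, 20.64, 2.04),
    c(0.00, 0.00, 0.09, 0.26, 0.81, 2.61, 1.46)
  )
  colnames(m) <- paste0("util_", util)
  ltc <- rbind(
    armd            = c(0.2, 1.6, 0.9, 1.9, 0.7, 2.8, 2.2, 1.9, 9.0, 0.2),
    arthritis       = c(0.2, 1.2, 1.2, 2.6, 0.8, 5.0, 1.2, 2.4, 5.7, 0.3),
    asthma          = c(7.1, 15.7, 13.6, 24.6, 10.3, 21.3, 16.2, 21.9, 11.8, 9.6),
    bipolar         = c(0.1, 0.4, 0.5, 2.7, 0.4, 1.3, 2.5, 0.8, 1.4, 0.1),
    chf             = c(0.1, 1.8, 2.1, 8.4, 0.5, 4.8, 2.2, 2.6, 14.9, 0.1),
    copd            = c(0.7, 7.1, 6.3, 20.6, 2.0, 12.9, 6.5, 12.2, 30.7, 0.5),
    crf             = c(1.1, 6.7, 5.7, 15.7, 3.2, 13.1, 5.6, 10.8, 31.0, 0.8),
    depression      = c(6.8, 15.4, 13.5, 28.7, 11.9, 17.7, 17.2, 16.8, 22.0, 8.5),
    diabetes        = c(2.1, 11.7, 8.2, 21.7, 5.3, 25.4, 13.3, 24.9, 24.8, 1.9),
    glaucoma        = c(0.5, 3.4, 1.5, 2.8, 1.3, 4.5, 2.0, 3.2, 9.5, 0.3),
    hypertension    = c(9.5, 33.4, 22.8, 39.2, 17.8, 46.6, 21.0, 49.5, 68.1, 7.2),
    hyperthyroidism = c(1.8, 7.4, 4.9, 11.1, 4.1, 11.7, 5.2, 11.5, 17.5, 1.6),
    ihd             = c(0.6, 7.6, 6.8, 19.8, 2.6, 17.5, 5.1, 11.7, 30.0, 0.8),
    low_back_pain   = c(1.1, 5.1, 3.6, 8.8, 2.2, 5.8, 2.8, 4.4, 5.4, 2.0),
    osteoporosis    = c(0.0, 0.8, 1.4, 5.8, 0.3, 2.1, 0.7, 0.4, 7.1, 0.0),
    parkinsons      = c(0.0, 0.1, 0.4, 1.1, 0.3, 1.1, 0.2, 0.5, 5.0, 0.0),
    schizophrenia   = c(0.4, 0.8, 1.6, 4.6, 0.9, 2.3, 10.7, 1.3, 4.5, 0.3),
    seizure         = c(0.8, 2.1, 4.0, 10.4, 1.2, 3.4, 2.2, 3.0, 4.7, 1.3)
  )
  ltc_t <- t(ltc)
  colnames(ltc_t) <- paste0("ltc_", rownames(ltc), "_pct")
  out <- tibble::tibble(
    segment = 1:10,
    n_people = c(39821L, 4720L, 4274L, 739L, 8899L, 2950L, 851L, 8836L,
                 423L, 8094L),
    age_mean = c(36.2, 53.6, 38.2, 47.5, 42.9, 59.3, 42.1, 60.4, 82.1, 29.8),
    age_sd = c(21.5, 20.5, 27.9, 27.3, 23.0, 21.4, 20.3, 18.5, 11.1, 20.0),
    deprived_pct = c(84.2, 85.7, 87.6, 88.6, 85.0, 85.2, 86.5, 86.1, 78.5, 85.6),
    smoker_pct = c(20.3, 23.1, 22.3, 27.2, 22.1, 22.1, 28.0, 25.9, 12.8, 20.6),
    risk_mean = c(0.07, 0.27, 0.23, 0.45, 0.20, 0.38, 0.36, 0.24, 0.50, 0.12),
    risk_sd = c(0.05, 0.13, 0.14, 0.19, 0.10, 0.15, 0.16, 0.12, 0.17, 0.08),
    ltc_count_mean = c(0.58, 2.55, 2.08, 5.27, 1.22, 3.75, 2.31, 2.89, 6.46, 0.64),
    frail_pct = c(0.4, 12.9, 9.5, 28.3, 4.0, 32.3, 11.8, 20.9, 66.0, 1.0),
    bed_days_elective = c(0.00, 0.64, 0.02, 0.21, 0.00, 0.10, 0.07, 0.00, 0.46, 0.00),
    bed_days_nonelective = c(0.00, 0.35, 3.21, 1.10, 0.07, 2.00, 1.76, 0.06, 11.90, 0.00),
    bed_days_maternity = c(0.01, 0.01, 0.04, 0.14, 0.05, 0.01, 1.26, 0.01, 0.00, 0.01),
    total_cost_m = c(3.2, 10.0, 8.7, 5.1, 4.2, 6.4, 2.0, 6.8, 2.3, 2.3),
    cost_per_head_gbp = c(79, 2121, 2025, 6912, 476, 2181, 2315, 772, 5489, 285),
    cost_ratio = c(0.12, 3.32, 3.15, 11.11, 0.74, 3.41, 3.55, 1.21, 9.20, 0.44),
    characterisation = c(
      "Low Need, Low Complex", "High Need, Low Complex",
      "Low Need, Low Complex", "High Need, High Complex",
      "Low Need, Low Complex", "High Need, High Complex",
      "High Need, Low Complex", "Low Need, Low Complex",
      "High Need, High Complex", "Low Need, Low Complex")
  )
  dplyr::bind_cols(out[, 1:2], tibble::as_tibble(m), out[, -(1:2)],
                   tibble::as_tibble(ltc_t))
}

#' Population-level reference means of the seven utilisation variables
#'
#' The whole-population mean annual counts that the need/complexity
#' rule-of-thumb compares segment means against, in the order of
#' [utilisation_settings()].
#'
#' @return A named numeric vector of length 7.
#' @export
reference_population_means <- function() {
  setNames(c(0.14, 0.08, 0.34, 0.91, 0.74, 4.75, 0.41), utilisation_settings())
}
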