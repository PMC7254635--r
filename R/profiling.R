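#' Profile segments
#'
#' Per-segment descriptive summaries in the style of a segment
#' characterisation table: size; mean and sample SD of each utilisation
#' variable, age, risk score and LTC count; proportions of smokers, deprived
#' (quintile 1-2), moderate-severe frailty and each long-term condition;
#' mean bed days by class; total cost, cost per head and the
#' cost-to-population ratio (segment share of total cost divided by segment
#' share of the population). A population row repeats every summary over the
#' whole cohort. Continuous/boolean summaries use non-missing values only;
#' columns absent from the cohort are skipped.
#'
#' @param cohort A validated cohort data frame.
#' @param assignment Either an integer vector (one segment id per row of
#'   `cohort`) or a tibble with `patient_id` and `segment`.
#' @return An object of class `popseg_profile`: `stats` (long tibble:
#'   `segment`, `variable`, `kind` (`"mean"`/`"proportion"`), `estimate`,
#'   `sd`, `n_obs`), `population` (same shape, whole cohort), `costs`
#'   (per-segment tibble with `n`, `pop_share`, `total_cost`,
#'   `cost_per_head`, `cost_share`, `cost_ratio`), and `n` (cohort size).
#' @export
profile_segments <- function(cohort, assignment) {
  cohort <- validate_cohort(cohort, strict = TRUE)
  seg <- resolve_assignment(cohort, assignment)
  if (anyNA(seg)) abort("Every patient must be assigned to a segment.")
  segs <- sort(unique(seg))
  if (any(tabulate(factor(seg, levels = segs)) == 0)) {
    abort("Empty segment in `assignment`.")
  }
  mean_vars <- intersect(
    c(utilisation_settings(), "age", "risk_score", "ltc_count",
      "bed_days_elective", "bed_days_nonelective", "bed_days_maternity",
      "cost_gbp"),
    names(cohort))
  prop_vars <- intersect(bool_cols(), names(cohort))
  summarise_group <- function(df, segment_label) {
    means <- purrr::map_dfr(mean_vars, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      tibble::tibble(variable = v, kind = "mean",
                     estimate = mean(x), sd = sd(x),
                     n_obs = length(x))
    })
    props <- purrr::map_dfr(prop_vars, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      tibble::tibble(variable = v, kind = "proportion",
                     estimate = mean(x), sd = NA_real_, n_obs = length(x))
    })
    dplyr::bind_rows(means, props) |>
      dplyr::mutate(segment = segment_label, .before = 1)
  }
  stats_tbl <- purrr::map_dfr(segs, function(s) {
    summarise_group(cohort[seg == s, , drop = FALSE], s)
  })
  population <- summarise_group(cohort, NA_integer_) |>
    dplyr::select(-"segment")
  n_total <- nrow(cohort)
  sizes <- as.vector(table(factor(seg, levels = segs)))
  costs <- tibble::tibble(segment = segs, n = sizes,
                          pop_share = sizes / n_total)
  if ("cost_gbp" %in% names(cohort)) {
    seg_cost <- as.vector(rowsum(dplyr::coalesce(cohort$cost_gbp, 0),
                                 factor(seg, levels = segs)))
    total <- sum(seg_cost)
    costs <- costs |>
      dplyr::mutate(
        total_cost = seg_cost,
        cost_per_head = seg_cost / sizes,
        cost_share = if (total > 0) seg_cost / total else NA_real_,
        cost_ratio = .data$cost_share / .data$pop_share)
  }
  structure(list(stats = stats_tbl, population = population, costs = costs,
                 n = n_total),
            class = "popseg_profile")
}

resolve_assignment <- function(cohort, assignment) {
  if (is.data.frame(assignment)) {
    if (!all(c("patient_id", "segment") %in% names(assignment))) {
      abort("`assignment` table needs `patient_id` and `segment` columns.")
    }
    idx <- match(cohort$patient_id, assignment$patient_id)
    if (anyNA(idx)) abort("Some patients have no segment assignment.")
    as.integer(assignment$segment[idx])
  } else {
    if (length(assignment) != nrow(cohort)) {
      abort("`assignment` must have one segment per patient.")
    }
    as.integer(assignment)
  }
}

#' Per-segment utilisation means in wide form
#'
#' Convenience accessor for [classify_segments()]: extracts the segment-level
#' mean of each of the seven utilisation settings from a profile.
#'
#' @param profile A [profile_segments()] result.
#' @return A tibble with `segment` and one column per utilisation setting.
#' @export
utilisation_profile_means <- function(profile) {
  stopifnot(inherits(profile, "popseg_profile"))
  profile$stats |>
    dplyr::filter(.data$variable %in% utilisation_settings(),
                  .data$kind == "mean") |>
    dplyr::select("segment", "variable", "estimate") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "estimate") |>
    dplyr::select("segment", dplyr::all_of(utilisation_settings()))
}

#' Population utilisation means from a profile
#'
#' @param profile A [profile_segments()] result.
#' @return Named numeric vector of the 7 population mean counts.
#' @export
population_utilisation_means <- function(profile) {
  stopifnot(inherits(profile, "popseg_profile"))
  pop <- profile$population
  v <- pop$estimate[match(utilisation_settings(), pop$variable)]
  setNames(v, utilisation_settings())
}

#' @export
print.popseg_profile <- function(x, ...) {
  cat("<popseg_profile> ", nrow(x$costs), " segments, n = ", x$n, "\n",
      sep = "")
  print(x$costs)
  invisible(x)
}

#' @export
tidy.popseg_profile <- function(x, ...) x$stats

#' @export
glance.popseg_profile <- function(x, ...) {
  tibble::tibble(n = x$n, k = nrow(x$costs),
                 largest_share = max(x$costs$pop_share))
}
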