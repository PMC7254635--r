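#' Segment-to-population utilisation ratios
#'
#' Divides a segment's mean annual count in each care setting by the study
#' population's mean. Settings with a zero population mean have no defined
#' ratio; they are flagged and excluded from threshold counting.
#'
#' @param segment_means Named (or ordered as [utilisation_settings()])
#'   non-negative numeric vector of a segment's mean counts.
#' @param population_means Population mean counts, same shape.
#' @return A tibble: `setting`, `segment_mean`, `population_mean`, `ratio`,
#'   `defined`.
#' @examples
#' utilisation_ratios(c(3.27, 0.36, 1.79, 4.22, 4.94, 15.9, 5.13),
#'                    reference_population_means())
#' @export
utilisation_ratios <- function(segment_means, population_means) {
  util <- utilisation_settings()
  segment_means <- as.numeric(segment_means)
  population_means <- as.numeric(population_means)
  if (length(segment_means) != 7 || length(population_means) != 7) {
    abort("Means must have one value per care setting (7).")
  }
  if (any(segment_means < 0) || any(population_means < 0)) {
    abort("Mean counts must be non-negative.")
  }
  defined <- population_means > 0
  ratio <- ifelse(defined, segment_means / population_means, NA_real_)
  tibble::tibble(setting = util, segment_mean = segment_means,
                 population_mean = population_means, ratio = ratio,
                 defined = defined)
}

#' Classify segments as high/low need and complexity
#'
#' Applies the mean-utilisation rule of thumb to each segment, taking the
#' wording literally with strict inequalities: a segment is **high need** if
#' (i) its mean count is more than 100% above the population mean in any one
#' care setting (ratio > `need_any_setting_ratio`, default 2), or (ii) more
#' than 20% above in 4 or more settings (ratio > `need_multi_setting_ratio`
#' in at least `need_multi_setting_min` settings); **high complexity** if its
#' mean count is above the population mean (ratio > `complexity_ratio`) in 4
#' or more settings. Settings without a defined ratio are excluded.
#'
#' @param segment_means A data frame with column `segment` and one column per
#'   utilisation setting of mean counts (e.g. from
#'   [utilisation_profile_means()]), or a matrix with 7 columns.
#' @param population_means Population mean counts (length 7).
#' @param config A [popseg_config()] carrying the thresholds.
#' @return A tibble of class `popseg_classification`: `segment`, `need`,
#'   `complexity` (`"high"`/`"low"`), `fired_need_any`, `fired_need_multi`,
#'   `fired_complexity` (list-columns of qualifying settings),
#'   `n_above_need_multi`, `n_above_complexity`.
#' @export
classify_segments <- function(segment_means, population_means,
                              config = popseg_config()) {
  util <- utilisation_settings()
  if (is.data.frame(segment_means)) {
    missing_cols <- setdiff(util, names(segment_means))
    if (length(missing_cols) > 0) {
      abort(paste0("`segment_means` is missing setting column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    seg_ids <- segment_means$segment %||% seq_len(nrow(segment_means))
    m <- as.matrix(segment_means[, util])
  } else {
    m <- as.matrix(segment_means)
    if (ncol(m) != 7) abort("`segment_means` must have 7 setting columns.")
    colnames(m) <- util
    seg_ids <- seq_len(nrow(m))
  }
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    rp <- utilisation_ratios(m[i, ], population_means)
    rp <- rp[rp$defined, ]
    any_hit <- rp$setting[rp$ratio > config$need_any_setting_ratio]
    multi_hit <- rp$setting[rp$ratio > config$need_multi_setting_ratio]
    cplx_hit <- rp$setting[rp$ratio > config$complexity_ratio]
    need_i <- length(any_hit) > 0
    need_ii <- length(multi_hit) >= config$need_multi_setting_min
    cplx <- length(cplx_hit) >= config$complexity_min_settings
    tibble::tibble(
      segment = seg_ids[i],
      need = if (need_i || need_ii) "high" else "low",
      complexity = if (cplx) "high" else "low",
      fired_need_any = list(any_hit),
      fired_need_multi = list(if (need_ii) multi_hit else character(0)),
      fired_complexity = list(if (cplx) cplx_hit else character(0)),
      n_above_need_multi = length(multi_hit),
      n_above_complexity = length(cplx_hit)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("popseg_classification", class(out))
  out
}

#' Compare classifications against a reference characterisation
#'
#' The literal rule of thumb need not agree with a published or a priori
#' characterisation of the same segments. This report puts the rule's output
#' next to the reference labels and flags every disagreement; the rule is
#' never overridden to match the reference.
#'
#' @param classification A [classify_segments()] result.
#' @param reference A data frame with columns `segment` and
#'   `characterisation` (strings such as `"High Need, Low Complex"`), e.g.
#'   `segment_reference_profiles()[, c("segment", "characterisation")]`.
#' @return A tibble: `segment`, `need`, `complexity`, `ref_need`,
#'   `ref_complexity`, `agree_need`, `agree_complexity`, `agree`.
#' @export
compare_characterisation <- function(classification, reference) {
  ref <- tibble::tibble(
    segment = reference$segment,
    ref_need = ifelse(grepl("high need", reference$characterisation,
                            ignore.case = TRUE), "high", "low"),
    ref_complexity = ifelse(grepl("high complex", reference$characterisation,
                                  ignore.case = TRUE), "high", "low"))
  dplyr::as_tibble(classification) |>
    dplyr::select("segment", "need", "complexity") |>
    dplyr::inner_join(ref, by = "segment") |>
    dplyr::mutate(
      agree_need = .data$need == .data$ref_need,
      agree_complexity = .data$complexity == .data$ref_complexity,
      agree = .data$agree_need & .data$agree_complexity)
}

#' @export
tidy.popseg_classification <- function(x, ...) {
  dplyr::as_tibble(x) |>
    dplyr::mutate(
      fired_need_any = purrr::map_chr(.data$fired_need_any, paste,
                                      collapse = ";"),
      fired_need_multi = purrr::map_chr(.data$fired_need_multi, paste,
                                        collapse = ";"),
      fired_complexity = purrr::map_chr(.data$fired_complexity, paste,
                                        collapse = ";"))
}
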