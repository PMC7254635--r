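#' Segment a cohort with k-means
#'
#' Standardises the seven utilisation variables, fits k-means with the
#' configured options, renumbers segments by decreasing size and returns the
#' fit together with the assignment table and centroids on both the
#' standardised and the raw count scale.
#'
#' @param cohort A validated cohort data frame.
#' @param k Number of segments (default `config$k_final`).
#' @param config A [popseg_config()].
#' @param standardizer Optional pre-fitted standardiser (defaults to fitting
#'   on `cohort`).
#' @return An object of class `popseg_segmentation`: `model`
#'   (`popseg_kmeans`), `standardizer`, `assignment` (tibble `patient_id`,
#'   `segment`), `centroids` (long tibble with standardised and raw values).
#' @export
segment_cohort <- function(cohort, k = NULL, config = popseg_config(),
                           standardizer = NULL) {
  cohort <- validate_cohort(cohort, strict = TRUE)
  k <- k %||% config$k_final
  if (is.null(standardizer)) standardizer <- fit_standardizer(cohort)
  z <- standardize_utilisation(cohort, standardizer)
  model <- kmeans_fit(z, k,
                      restarts = config$kmeans$restarts,
                      tol = config$kmeans$tol,
                      max_iter = config$kmeans$max_iter,
                      init = if (config$kmeans$init == "random") "random"
                             else "kmeans++",
                      seed = config$seed)
  model <- relabel_by_size(model)
  raw <- unstandardize_utilisation(model$centroids, standardizer)
  centroids <- tidy(model) |>
    dplyr::left_join(
      tibble::as_tibble(raw) |>
        dplyr::mutate(segment = seq_len(model$k)) |>
        tidyr::pivot_longer(-"segment", names_to = "variable",
                            values_to = "centroid_raw"),
      by = c("segment", "variable"))
  structure(list(
    model = model,
    standardizer = standardizer,
    assignment = tibble::tibble(patient_id = cohort$patient_id,
                                segment = model$assignment),
    centroids = centroids
  ), class = "popseg_segmentation")
}

#' @export
print.popseg_segmentation <- function(x, ...) {
  cat("<popseg_segmentation>\n")
  print(x$model)
  invisible(x)
}

#' @export
tidy.popseg_segmentation <- function(x, ...) x$centroids

#' @export
glance.popseg_segmentation <- function(x, ...) glance(x$model)
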