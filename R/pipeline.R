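#' Run the end-to-end segmentation pipeline
#'
#' Orchestrates the full analysis on a cohort: (optionally) choose the number
#' of segments by subsampled hierarchical clustering, fit k-means on the
#' standardised utilisation variables, renumber segments by size, classify
#' each segment as high/low need and complexity, profile the segments and run
#' the statistical test battery. All randomness derives from `config$seed`,
#' so a re-run with the same inputs reproduces every output.
#'
#' @param cohort A cohort data frame (e.g. from [read_cohort()] or
#'   [generate_cohort()]).
#' @param config A [popseg_config()].
#' @param k Override the number of segments and skip selection; `NULL`
#'   (default) runs [select_k()].
#' @param out_dir Optional directory; when given, assignments, centroids,
#'   k-selection trace, classification, profile, test results and a JSON run
#'   manifest are written there as CSV/JSON.
#' @param reference Optional reference characterisation (columns `segment`,
#'   `characterisation`) to diff the rule-based labels against.
#' @return An object of class `popseg_run`: `k`, `kselect` (or `NULL`),
#'   `segmentation`, `classification`, `discrepancy` (or `NULL`), `profile`,
#'   `tests`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = popseg_config(), k = NULL,
                         out_dir = NULL, reference = NULL) {
  cohort <- validate_cohort(cohort, strict = TRUE)
  stage <- "k selection"
  result <- tryCatch({
    kselect <- NULL
    if (is.null(k)) {
      kselect <- select_k(cohort, config)
      k <- kselect$k
    }
    stage <- "k-means segmentation"
    segmentation <- segment_cohort(cohort, k = k, config = config)
    stage <- "profiling"
    profile <- profile_segments(cohort, segmentation$assignment)
    stage <- "need/complexity classification"
    classification <- classify_segments(
      utilisation_profile_means(profile),
      population_utilisation_means(profile), config)
    discrepancy <- if (!is.null(reference)) {
      compare_characterisation(classification, reference)
    }
    stage <- "test battery"
    tests <- run_test_battery(cohort, segmentation$assignment,
                              alpha = config$alpha)
    list(kselect = kselect, segmentation = segmentation,
         profile = profile, classification = classification,
         discrepancy = discrepancy, tests = tests, k = k)
  }, error = function(e) {
    abort(paste0("Pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  manifest <- build_manifest(cohort, config, result)
  run <- structure(c(result, list(manifest = manifest)),
                   class = "popseg_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

build_manifest <- function(cohort, config, result) {
  num_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  fingerprint <- list(
    n = nrow(cohort),
    columns = names(cohort),
    column_sums = purrr::map(setNames(num_cols, num_cols),
                             ~ sum(as.numeric(cohort[[.x]]), na.rm = TRUE)))
  list(
    package_version = as.character(packageVersion("popsegment")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input = fingerprint,
    k = result$k,
    k_selection = if (!is.null(result$kselect)) {
      list(suggestions = result$kselect$suggestions$suggested_k,
           abstained = result$kselect$abstained)
    },
    objective = result$segmentation$model$objective,
    converged = result$segmentation$model$converged,
    segment_sizes = result$segmentation$model$sizes
  )
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    written <<- c(written, name)
  }
  emit(run$segmentation$assignment, "assignments.csv")
  emit(run$segmentation$centroids, "centroids.csv")
  if (!is.null(run$kselect)) emit(tidy(run$kselect), "kselect_trace.csv")
  emit(tidy(run$classification), "classification.csv")
  if (!is.null(run$discrepancy)) emit(run$discrepancy, "discrepancy.csv")
  emit(run$profile$stats, "profile_segments.csv")
  emit(run$profile$population, "profile_population.csv")
  emit(run$profile$costs, "profile_costs.csv")
  emit(run$tests$global, "tests_global.csv")
  emit(run$tests$pairwise, "tests_pairwise.csv")
  emit(run$tests$annotations, "tests_annotations.csv")
  manifest <- run$manifest
  manifest$files <- written
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(written)
}

#' @export
print.popseg_run <- function(x, ...) {
  cat("<popseg_run> k =", x$k, "\n")
  if (!is.null(x$kselect)) {
    cat("  selection suggestions:",
        paste(x$kselect$suggestions$suggested_k, collapse = ", "), "\n")
  }
  cat("  segment sizes:",
      paste(x$segmentation$model$sizes, collapse = ", "), "\n")
  lab <- tidy(x$classification)
  cat("  need/complexity:",
      paste(paste0(lab$segment, ":", substr(lab$need, 1, 1),
                   substr(lab$complexity, 1, 1)), collapse = " "), "\n")
  invisible(x)
}

#' @export
glance.popseg_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(k = x$k, n = x$manifest$input$n,
                   objective = x$manifest$objective),
    glance(x$tests)[, c("alpha_adjusted", "n_significant")])
}
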