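#' Analysis configuration
#'
#' Collects every tunable of the segmentation pipeline with the defaults used
#' throughout: k selection over 10 random subsets of 3,000 patients across a
#' candidate range of 2-20 clusters, Ward linkage, a final k of 10, the
#' need/complexity rule thresholds (ratios to the population mean utilisation),
#' and the 0.05 significance level that the pairwise battery Bonferroni-adjusts.
#'
#' @param k_final Number of segments fitted when selection is skipped.
#' @param n_subsets Number of random subsets used for k selection.
#' @param subset_size Patients per subset (must not exceed the cohort size).
#' @param k_range Inclusive integer range of candidate cluster counts
#'   (lower bound at least 2).
#' @param seed Integer seed; every source of randomness derives from it.
#' @param need_any_setting_ratio A segment is high need if its mean count in
#'   any one care setting exceeds this multiple of the population mean
#'   (default 2, i.e. more than 100% above).
#' @param need_multi_setting_ratio,need_multi_setting_min Alternative high-need
#'   route: mean count above `need_multi_setting_ratio` times the population
#'   mean (default 1.2, more than 20% above) in at least
#'   `need_multi_setting_min` settings (default 4).
#' @param complexity_ratio,complexity_min_settings High complexity: mean count
#'   above `complexity_ratio` times the population mean (default 1) in at
#'   least `complexity_min_settings` settings (default 4).
#' @param alpha Family significance level before Bonferroni adjustment.
#' @param linkage Hierarchical linkage: `"ward"`, `"average"` or `"complete"`.
#' @param kmeans List of k-means options: `init` (`"kmeans++"` or
#'   `"random"`), `restarts`, `tol` (relative objective change declaring
#'   convergence) and `max_iter`.
#' @return A list of class `popseg_config`.
#' @seealso [load_config()] to read the same fields from a YAML file.
#' @export
popseg_config <- function(k_final = 10L,
                          n_subsets = 10L,
                          subset_size = 3000L,
                          k_range = c(2L, 20L),
                          seed = 1L,
                          need_any_setting_ratio = 2,
                          need_multi_setting_ratio = 1.2,
                          need_multi_setting_min = 4L,
                          complexity_ratio = 1,
                          complexity_min_settings = 4L,
                          alpha = 0.05,
                          linkage = c("ward", "average", "complete"),
                          kmeans = list()) {
  linkage <- match.arg(linkage)
  km_defaults <- list(init = "kmeans++", restarts = 10L, tol = 1e-6,
                     max_iter = 300L)
  if (!is.list(kmeans)) abort("`kmeans` must be a list of options.")
  unknown <- setdiff(names(kmeans), names(km_defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown kmeans option(s): ", paste(unknown, collapse = ", ")))
  }
  km <- utils::modifyList(km_defaults, kmeans)
  cfg <- structure(list(
    k_final = as.integer(k_final),
    n_subsets = as.integer(n_subsets),
    subset_size = as.integer(subset_size),
    k_range = as.integer(k_range),
    seed = as.integer(seed),
    need_any_setting_ratio = as.numeric(need_any_setting_ratio),
    need_multi_setting_ratio = as.numeric(need_multi_setting_ratio),
    need_multi_setting_min = as.integer(need_multi_setting_min),
    complexity_ratio = as.numeric(complexity_ratio),
    complexity_min_settings = as.integer(complexity_min_settings),
    alpha = as.numeric(alpha),
    linkage = linkage,
    kmeans = km
  ), class = "popseg_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("Invalid configuration: ", msg))
  chk(cfg$k_final >= 1, "`k_final` must be a positive integer.")
  chk(cfg$n_subsets >= 1, "`n_subsets` must be a positive integer.")
  chk(cfg$subset_size >= 1, "`subset_size` must be a positive integer.")
  chk(length(cfg$k_range) == 2 && cfg$k_range[1] >= 2 &&
        cfg$k_range[2] >= cfg$k_range[1],
      "`k_range` must be an increasing pair with lower bound >= 2.")
  chk(cfg$need_any_setting_ratio > 0, "`need_any_setting_ratio` must be > 0.")
  chk(cfg$need_multi_setting_ratio > 0, "`need_multi_setting_ratio` must be > 0.")
  chk(cfg$need_multi_setting_min >= 1, "`need_multi_setting_min` must be >= 1.")
  chk(cfg$complexity_ratio > 0, "`complexity_ratio` must be > 0.")
  chk(cfg$complexity_min_settings >= 1, "`complexity_min_settings` must be >= 1.")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "`alpha` must lie in (0, 1).")
  chk(cfg$kmeans$restarts >= 1, "kmeans `restarts` must be >= 1.")
  chk(cfg$kmeans$tol > 0, "kmeans `tol` must be > 0.")
  chk(cfg$kmeans$max_iter >= 1, "kmeans `max_iter` must be >= 1.")
  chk(cfg$kmeans$init %in% c("kmeans++", "random"),
      "kmeans `init` must be \"kmeans++\" or \"random\".")
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML document whose keys mirror the arguments of [popseg_config()]
#' (the `kmeans` block may be nested). Unspecified keys take the defaults;
#' every value is range-checked. An empty file yields the default
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return A `popseg_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) abort("Config file must be a YAML mapping.")
  known <- names(formals(popseg_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$k_range)) vals$k_range <- as.integer(unlist(vals$k_range))
  do.call(popseg_config, vals)
}

#' @export
print.popseg_config <- function(x, ...) {
  cat("<popseg_config>\n")
  cat("  k selection: ", x$n_subsets, " subsets of ", x$subset_size,
      ", k in [", x$k_range[1], ", ", x$k_range[2], "], ", x$linkage,
      " linkage\n", sep = "")
  cat("  k-means: k_final=", x$k_final, ", init=", x$kmeans$init,
      ", restarts=", x$kmeans$restarts, "\n", sep = "")
  cat("  need/complexity ratios: >", x$need_any_setting_ratio, " any; >",
      x$need_multi_setting_ratio, " in >=", x$need_multi_setting_min,
      "; complexity >", x$complexity_ratio, " in >=",
      x$complexity_min_settings, "\n", sep = "")
  cat("  alpha=", x$alpha, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# Deterministic per-stage seed derivation from the single run seed. Offsets
# are fixed per stage so partial re-runs reproduce: 1 = k selection subsets,
# 2 = k-means restarts, 3 = cohort synthesis, 4 = planted clusters.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1000003) %% 2147483647)
}
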