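#' Choose the number of segments by subsampled hierarchical clustering
#'
#' Draws `n_subsets` random subsets of `subset_size` patients (without
#' replacement within a subset; subsets independent), builds an agglomerative
#' tree on each, and records for every candidate k in `k_range` the
#' Calinski-Harabasz pseudo-F of the k-group cut and the Duda-Hart/pseudo-T^2
#' diagnostics of the split taking k to k + 1 groups. The stopping pattern
#' sought is a high Duda-Hart index with a low pseudo-T^2 where the
#' preceding pseudo-T^2 is high: strong evidence against stopping at g - 1
#' groups followed by no evidence for splitting beyond g. A candidate g is
#' therefore flagged in a subset when `pseudo_t2(g) < pseudo_t2(g - 1)` and
#' `dh_index(g) > dh_index(g - 1)`, and the subset suggests the flagged g
#' with the largest evidence contrast `pseudo_t2(g - 1) / pseudo_t2(g)`
#' (ties to the smallest g); subsets with no flagged candidate abstain. The
#' consensus k is the median of the suggestions, half-integer medians
#' resolved toward the modal suggestion. A plain local-minimum criterion on
#' pseudo-T^2 would not do: the statistic scales with the size of the
#' cluster being split, so it keeps falling past the true k; the true k
#' appears as a cliff in the trace, which the contrast measures directly.
#'
#' Standardisation uses the full cohort's means and SDs so every subset is
#' measured on the same scale.
#'
#' @param cohort A validated cohort data frame.
#' @param config A [popseg_config()]; `n_subsets`, `subset_size`, `k_range`,
#'   `linkage` and `seed` are used.
#' @return An object of class `popseg_kselect`: `k` (consensus choice),
#'   `suggestions` (per-subset tibble), `trace` (per subset and k: pseudo-F,
#'   Duda-Hart record, flagged), and the subset membership indices.
#' @export
select_k <- function(cohort, config = popseg_config()) {
  cohort <- validate_cohort(cohort, strict = TRUE)
  n <- nrow(cohort)
  if (config$subset_size > n) {
    abort("`subset_size` exceeds the cohort size.")
  }
  std <- fit_standardizer(cohort)
  z <- standardize_utilisation(cohort, std)
  k_lo <- config$k_range[1]
  k_hi <- config$k_range[2]
  g_grid <- seq(max(1L, k_lo - 1L), k_hi + 1L)
  traces <- vector("list", config$n_subsets)
  members <- vector("list", config$n_subsets)
  for (s in seq_len(config$n_subsets)) {
    sseed <- stage_seed(config$seed, 1) + s
    idx <- withr::with_seed(sseed, sample.int(n, config$subset_size))
    members[[s]] <- idx
    pts <- z[idx, , drop = FALSE]
    tree <- build_tree(pts, linkage = config$linkage)
    dh <- purrr::map_dfr(g_grid, function(g) duda_hart(tree, g))
    labels <- cutree(tree$hclust, k = g_grid)
    pf <- vapply(seq_along(g_grid), function(i) {
      g <- g_grid[i]
      if (g < 2 || g > nrow(pts) - 1) return(NA_real_)
      ch_pseudo_f(pts, labels[, i])
    }, numeric(1))
    tr <- dplyr::mutate(dh, subset = s, pseudo_f = pf, .before = 1)
    traces[[s]] <- flag_candidates(tr, k_lo, k_hi)
  }
  trace <- dplyr::bind_rows(traces)
  suggestions <- trace |>
    dplyr::filter(.data$flagged) |>
    dplyr::group_by(.data$subset) |>
    dplyr::arrange(dplyr::desc(.data$t2_contrast), .data$g,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("subset", suggested_k = "g", "dh_index", "pseudo_t2",
                  "t2_contrast")
  abstained <- setdiff(seq_len(config$n_subsets), suggestions$subset)
  if (nrow(suggestions) == 0) {
    abort(paste0("No subset flagged a stopping point; the stopping-rule ",
                 "pattern is absent. Inspect the trace and choose k manually."))
  }
  k <- consensus_k(suggestions$suggested_k)
  structure(list(
    k = k,
    suggestions = suggestions,
    abstained = abstained,
    trace = trace,
    members = members,
    k_range = c(k_lo, k_hi),
    linkage = config$linkage,
    seed = config$seed
  ), class = "popseg_kselect")
}

# Flag g in [k_lo, k_hi] where pseudo-T^2 drops relative to g - 1 and the
# Duda-Hart index rises; t2_contrast = t2(g-1)/t2(g) measures how sharply the
# evidence for further splitting collapses at g.
flag_candidates <- function(tr, k_lo, k_hi) {
  t2 <- tr$pseudo_t2
  dh <- tr$dh_index
  g <- tr$g
  flagged <- rep(FALSE, nrow(tr))
  contrast <- rep(NA_real_, nrow(tr))
  for (i in seq_along(g)) {
    if (g[i] < k_lo || g[i] > k_hi) next
    im <- match(g[i] - 1L, g)
    if (is.na(im)) next
    vals <- c(t2[i], t2[im], dh[i], dh[im])
    if (anyNA(vals)) next
    flagged[i] <- t2[i] < t2[im] && dh[i] > dh[im]
    if (flagged[i]) {
      contrast[i] <- if (t2[i] > 0) t2[im] / t2[i] else Inf
    }
  }
  tr$flagged <- flagged
  tr$t2_contrast <- contrast
  tr
}

# Median of integer suggestions; a half-integer median resolves to whichever
# neighbour is the more frequent suggestion (ties to the smaller).
consensus_k <- function(ks) {
  med <- median(ks)
  if (med == round(med)) return(as.integer(med))
  lo <- floor(med); hi <- ceiling(med)
  n_lo <- sum(ks == lo); n_hi <- sum(ks == hi)
  as.integer(if (n_hi > n_lo) hi else lo)
}

#' @export
print.popseg_kselect <- function(x, ...) {
  cat("<popseg_kselect>\n")
  cat("  consensus k:", x$k, " (range searched: [", x$k_range[1], ",",
      x$k_range[2], "],", x$linkage, "linkage )\n")
  cat("  per-subset suggestions:",
      paste(x$suggestions$suggested_k, collapse = ", "), "\n")
  if (length(x$abstained)) {
    cat("  abstaining subsets:", paste(x$abstained, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.popseg_kselect <- function(x, ...) {
  dplyr::select(x$trace, "subset", "g", "pseudo_f", "je1", "je2",
                "dh_index", "pseudo_t2", "t2_contrast", "n1", "n2",
                "flagged")
}

#' @export
glance.popseg_kselect <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_subsets = length(x$members),
    n_abstained = length(x$abstained),
    min_suggestion = min(x$suggestions$suggested_k),
    max_suggestion = max(x$suggestions$suggested_k)
  )
}
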