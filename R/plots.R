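#' Plot the k-selection trace
#'
#' Two stacked panels against the candidate number of clusters: the
#' Calinski-Harabasz pseudo-F (one line per subset) and the Duda-Hart
#' pseudo-T^2 with flagged stopping candidates marked. The stopping pattern
#' to look for is a low pseudo-T^2 flanked by high values.
#'
#' @param object A `popseg_kselect` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.popseg_kselect <- function(object, ...) {
  tr <- tidy(object) |>
    tidyr::pivot_longer(c("pseudo_f", "pseudo_t2"), names_to = "index",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(index = dplyr::recode(.data$index,
                                        pseudo_f = "Calinski-Harabasz pseudo-F",
                                        pseudo_t2 = "Duda-Hart pseudo-T²"))
  flagged <- dplyr::filter(tr, .data$flagged,
                           .data$index == "Duda-Hart pseudo-T²")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$g, y = .data$value,
                                   group = .data$subset)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(data = flagged, colour = "red", size = 2) +
    ggplot2::facet_wrap(~index, ncol = 1, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "Number of clusters",
                  y = "Index value",
                  title = paste0("Cluster-number selection (consensus k = ",
                                 object$k, ")"),
                  subtitle = "One line per random subset; red: flagged stopping candidates")
}

#' Plot segment centroids
#'
#' Heat map of the fitted centroids in standardised (z-score) units:
#' segments by care setting, the fingerprint of each utilisation pattern.
#'
#' @param object A `popseg_segmentation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.popseg_segmentation <- function(object, ...) {
  ctr <- object$centroids
  ggplot2::ggplot(ctr, ggplot2::aes(x = .data$variable,
                                    y = factor(.data$segment),
                                    fill = .data$centroid)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0,
                                  name = "z-score") +
    ggplot2::labs(x = "Care setting", y = "Segment",
                  title = "Segment centroids (standardised utilisation)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot per-segment cost concentration
#'
#' Bar chart of the cost-to-population ratio per segment (share of total
#' cost over share of patients; above 1 means disproportionate spend).
#'
#' @param object A `popseg_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.popseg_profile <- function(object, ...) {
  if (!"cost_ratio" %in% names(object$costs)) {
    abort("Profile has no cost information (`cost_gbp` column absent).")
  }
  ggplot2::ggplot(object$costs,
                  ggplot2::aes(x = factor(.data$segment),
                               y = .data$cost_ratio)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Segment", y = "Cost-to-population ratio",
                  title = "Cost concentration by segment")
}
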