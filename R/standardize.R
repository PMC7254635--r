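#' Fit the utilisation standardiser
#'
#' Clustering distances weight every care setting equally, so each of the
#' seven utilisation variables is z-scored: centred on its sample mean and
#' scaled by its sample SD (denominator n - 1). A zero-variance variable
#' would receive infinite weight and is an error.
#'
#' @param cohort A cohort data frame containing the seven utilisation columns.
#' @return An object of class `popseg_standardizer` with fields `mu` and
#'   `sigma` (named length-7 vectors).
#' @export
fit_standardizer <- function(cohort) {
  util <- utilisation_settings()
  missing_cols <- setdiff(util, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing utilisation column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cohort) < 2) abort("At least 2 records are needed.")
  x <- as.matrix(cohort[, util])
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  zero <- sigma <= 0 | !is.finite(sigma)
  if (any(zero)) {
    abort(paste0("Zero variance in utilisation variable(s): ",
                 paste(util[zero], collapse = ", ")))
  }
  structure(list(mu = mu, sigma = sigma), class = "popseg_standardizer")
}

#' Standardise the utilisation variables
#'
#' Applies `z = (x - mu) / sigma` elementwise with the fitted means and SDs.
#'
#' @param cohort A cohort data frame.
#' @param standardizer A fitted [fit_standardizer()] object; fitted on
#'   `cohort` itself when omitted.
#' @return A numeric matrix (n x 7) of z-scores with the utilisation column
#'   names.
#' @export
standardize_utilisation <- function(cohort, standardizer = NULL) {
  if (is.null(standardizer)) standardizer <- fit_standardizer(cohort)
  if (!inherits(standardizer, "popseg_standardizer")) {
    abort("`standardizer` must come from fit_standardizer().")
  }
  x <- as.matrix(cohort[, utilisation_settings()])
  sweep(sweep(x, 2, standardizer$mu, "-"), 2, standardizer$sigma, "/")
}

#' Invert the standardisation
#'
#' @param z A matrix of z-scores as produced by [standardize_utilisation()].
#' @param standardizer The `popseg_standardizer` used to produce `z`.
#' @return The matrix on the raw count scale.
#' @export
unstandardize_utilisation <- function(z, standardizer) {
  sweep(sweep(as.matrix(z), 2, standardizer$sigma, "*"), 2,
        standardizer$mu, "+")
}

#' @export
print.popseg_standardizer <- function(x, ...) {
  cat("<popseg_standardizer>\n")
  print(round(rbind(mu = x$mu, sigma = x$sigma), 4))
  invisible(x)
}
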