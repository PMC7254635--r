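#' Bonferroni-adjusted pairwise significance level
#'
#' The pairwise battery compares each segment against each of the other
#' `k - 1` segments, so the family for one segment and variable has `k - 1`
#' comparisons and the adjusted level is `alpha / (k - 1)` (0.05/9 = 0.0056
#' at ten segments).
#'
#' @param alpha Family significance level.
#' @param k Number of segments.
#' @return The adjusted per-comparison level.
#' @export
bonferroni_alpha <- function(alpha = 0.05, k = 10L) {
  if (k < 2) abort("`k` must be at least 2.")
  alpha / (k - 1)
}

#' Which tests apply to a variable
#'
#' Count-like variables (the seven utilisation settings and the LTC count)
#' are non-Normal, so differences across segments use a Kruskal-Wallis test
#' globally and Mann-Whitney U pairwise. Age and the emergency-admission risk
#' score use ANOVA globally and t-tests pairwise. Proportions (smoking,
#' deprivation, frailty, each LTC flag) use a chi-square test globally and a
#' pooled two-proportion z-test pairwise.
#'
#' @param variable A schema column name.
#' @return A tibble: `variable`, `family` (`"count"`, `"normal"`,
#'   `"proportion"`), `global_test`, `pairwise_test`.
#' @examples
#' variable_test_plan("gp_visits")
#' @export
variable_test_plan <- function(variable) {
  counts <- c(utilisation_settings(), "ltc_count")
  normals <- c("age", "risk_score")
  props <- bool_cols()
  if (variable %in% counts) {
    fam <- c("count", "kruskal_wallis", "mann_whitney")
  } else if (variable %in% normals) {
    fam <- c("normal", "anova", "t_test")
  } else if (variable %in% props) {
    fam <- c("proportion", "chi_square", "z_test")
  } else {
    abort(paste0("No test plan for variable `", variable, "`."))
  }
  tibble::tibble(variable = variable, family = fam[1],
                 global_test = fam[2], pairwise_test = fam[3])
}

# Pooled two-proportion z (no continuity correction). Returns c(statistic, p).
two_prop_z <- function(x1, n1, x2, n2) {
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  if (se == 0) return(c(statistic = 0, p_value = 1))
  z <- (x1 / n1 - x2 / n2) / se
  c(statistic = z, p_value = 2 * pnorm(-abs(z)))
}

pairwise_stat <- function(test, xa, xb) {
  out <- tryCatch(switch(
    test,
    mann_whitney = {
      ht <- suppressWarnings(
        wilcox.test(xa, xb, exact = FALSE, correct = FALSE))
      c(unname(ht$statistic), ht$p.value)
    },
    t_test = {
      ht <- t.test(xa, xb)
      c(unname(ht$statistic), ht$p.value)
    },
    t_test_pooled = {
      ht <- t.test(xa, xb, var.equal = TRUE)
      c(unname(ht$statistic), ht$p.value)
    },
    z_test = {
      z <- two_prop_z(sum(xa), length(xa), sum(xb), length(xb))
      unname(z)
    }
  ), error = function(e) c(NA_real_, NA_real_))
  names(out) <- c("statistic", "p_value")
  out
}

global_stat <- function(test, values, seg) {
  out <- tryCatch(switch(
    test,
    kruskal_wallis = {
      ht <- kruskal.test(values, factor(seg))
      c(unname(ht$statistic), ht$p.value)
    },
    anova = {
      ht <- oneway.test(values ~ factor(seg), var.equal = TRUE)
      c(unname(ht$statistic), ht$p.value)
    },
    chi_square = {
      tab <- table(factor(seg), factor(values, levels = c(FALSE, TRUE)))
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      c(unname(ht$statistic), ht$p.value)
    }
  ), error = function(e) c(NA_real_, NA_real_))
  names(out) <- c("statistic", "p_value")
  out
}

#' Run the segment-profiling test battery
#'
#' Global tests of difference across all segments for every profiled
#' variable, followed by two-sided pairwise tests between every segment
#' pair, flagged at the Bonferroni-adjusted level `alpha / (k - 1)`.
#' Mann-Whitney uses the tie-corrected large-sample normal approximation
#' without continuity correction; t-tests use the Welch correction by
#' default; two-proportion z-tests pool the variance. For each variable and
#' segment the report counts how many other segments differ significantly
#' (`differs_from`) and assigns the annotation tier: `"x"` differs from all
#' `k - 1` others, `"y"` from `k - 2`, `"z"` from `k - 3`.
#'
#' @param cohort A validated cohort data frame.
#' @param assignment Segment assignment (vector or `patient_id`/`segment`
#'   tibble).
#' @param alpha Family significance level (default 0.05).
#' @param variables Variables to test; defaults to every profiled column
#'   present in the cohort.
#' @param pooled_t Use pooled-variance t-tests instead of Welch.
#' @return An object of class `popseg_tests`: `global`, `pairwise`,
#'   `annotations` tibbles plus `alpha`, `alpha_adjusted`, `k`.
#' @export
run_test_battery <- function(cohort, assignment, alpha = 0.05,
                             variables = NULL, pooled_t = FALSE) {
  cohort <- validate_cohort(cohort, strict = TRUE)
  seg <- resolve_assignment(cohort, assignment)
  segs <- sort(unique(seg))
  k <- length(segs)
  if (k < 2) abort("At least 2 segments are required.")
  if (is.null(variables)) {
    variables <- intersect(
      c(utilisation_settings(), "ltc_count", "age", "risk_score",
        bool_cols()),
      names(cohort))
  }
  alpha_adj <- bonferroni_alpha(alpha, k)
  plans <- purrr::map_dfr(variables, variable_test_plan)
  pairs <- utils::combn(segs, 2)
  global <- purrr::map_dfr(seq_len(nrow(plans)), function(i) {
    v <- plans$variable[i]
    x <- cohort[[v]]
    keep <- !is.na(x)
    gs <- global_stat(plans$global_test[i], x[keep], seg[keep])
    tibble::tibble(variable = v, test = plans$global_test[i],
                   statistic = gs[["statistic"]], p_value = gs[["p_value"]])
  })
  pairwise <- purrr::map_dfr(seq_len(nrow(plans)), function(i) {
    v <- plans$variable[i]
    test <- plans$pairwise_test[i]
    if (test == "t_test" && pooled_t) test <- "t_test_pooled"
    x <- cohort[[v]]
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      xa <- x[seg == a & !is.na(x)]
      xb <- x[seg == b & !is.na(x)]
      res <- if (plans$family[i] != "proportion" &&
                 (length(xa) < 2 || length(xb) < 2)) {
        c(statistic = NA_real_, p_value = NA_real_)
      } else {
        pairwise_stat(test, xa, xb)
      }
      tibble::tibble(variable = v, test = plans$pairwise_test[i],
                     seg_a = a, seg_b = b,
                     statistic = res[["statistic"]],
                     p_value = res[["p_value"]],
                     significant = !is.na(res[["p_value"]]) &&
                       res[["p_value"]] < alpha_adj)
    })
  })
  annotations <- pairwise |>
    tidyr::pivot_longer(c("seg_a", "seg_b"), values_to = "segment") |>
    dplyr::group_by(.data$variable, .data$segment) |>
    dplyr::summarise(differs_from = sum(.data$significant),
                     .groups = "drop") |>
    dplyr::mutate(tier = dplyr::case_when(
      .data$differs_from == k - 1 ~ "x",
      .data$differs_from == k - 2 ~ "y",
      .data$differs_from == k - 3 ~ "z",
      TRUE ~ NA_character_))
  structure(list(global = global, pairwise = pairwise,
                 annotations = annotations, alpha = alpha,
                 alpha_adjusted = alpha_adj, k = k),
            class = "popseg_tests")
}

#' Pairwise p-values of one variable as a symmetric matrix
#'
#' @param tests A [run_test_battery()] result.
#' @param variable Variable name.
#' @return A k x k symmetric matrix of pairwise p-values (diagonal `NA`).
#' @export
pairwise_p_matrix <- function(tests, variable) {
  stopifnot(inherits(tests, "popseg_tests"))
  pw <- dplyr::filter(tests$pairwise, .data$variable == !!variable)
  segs <- sort(unique(c(pw$seg_a, pw$seg_b)))
  m <- matrix(NA_real_, length(segs), length(segs),
              dimnames = list(segs, segs))
  for (i in seq_len(nrow(pw))) {
    a <- as.character(pw$seg_a[i]); b <- as.character(pw$seg_b[i])
    m[a, b] <- m[b, a] <- pw$p_value[i]
  }
  m
}

#' @export
print.popseg_tests <- function(x, ...) {
  cat("<popseg_tests> k =", x$k, " adjusted alpha =",
      format(x$alpha_adjusted, digits = 3), "\n")
  print(x$global, n = 10)
  invisible(x)
}

#' @export
tidy.popseg_tests <- function(x, ...) x$global

#' @export
glance.popseg_tests <- function(x, ...) {
  tibble::tibble(
    k = x$k, alpha = x$alpha, alpha_adjusted = x$alpha_adjusted,
    n_variables = nrow(x$global),
    n_pairwise = nrow(x$pairwise),
    n_significant = sum(x$pairwise$significant, na.rm = TRUE))
}
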