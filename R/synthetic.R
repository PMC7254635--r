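#' Specify one synthetic segment
#'
#' A segment is a mixture component: patients drawn from it share the same
#' negative-binomial utilisation means, demographic distributions, long-term
#' condition prevalences and cost model. Count variables use a negative
#' binomial with variance `m + m^2 / dispersion` (degenerate at zero when the
#' mean is zero), because observed utilisation SDs exceed their means.
#'
#' @param weight Mixture weight (normalised across segments at generation).
#' @param util_means Named or ordered numeric vector of 7 non-negative mean
#'   annual counts, one per [utilisation_settings()].
#' @param util_dispersion Negative-binomial dispersion (size) parameter.
#' @param age_mean,age_sd Age distribution (normal, truncated to `[0, 105]`).
#' @param smoker_p,deprived_p,frail_p Bernoulli probabilities.
#' @param ltc_prevalence Named probabilities per condition in
#'   [ltc_conditions()] (missing conditions default to 0).
#' @param ltc_count_mean Mean total long-term-condition count
#'   (negative binomial).
#' @param risk_mean,risk_sd Emergency-admission risk score moments; a beta
#'   distribution is moment-matched, so `risk_sd^2 < risk_mean (1 - risk_mean)`
#'   is required.
#' @param cost_unit_prices GBP per unit of each of the 7 activities; annual
#'   cost is their inner product with the counts plus half-normal noise of
#'   scale `cost_noise_sd`.
#' @param cost_noise_sd Half-normal cost noise scale in GBP.
#' @param bed_days_means Mean annual elective/non-elective/maternity bed days
#'   (negative binomial, dispersion shared with utilisation).
#' @return A list of class `popseg_segment_spec`.
#' @export
segment_spec <- function(weight,
                         util_means,
                         util_dispersion = 1,
                         age_mean = 40, age_sd = 20,
                         smoker_p = 0.2, deprived_p = 0.5, frail_p = 0.05,
                         ltc_prevalence = NULL,
                         ltc_count_mean = 1,
                         risk_mean = 0.15, risk_sd = 0.1,
                         cost_unit_prices = default_unit_prices(),
                         cost_noise_sd = 50,
                         bed_days_means = c(elective = 0, nonelective = 0,
                                            maternity = 0)) {
  util <- utilisation_settings()
  util_means <- as.numeric(util_means)
  if (length(util_means) != 7 || any(util_means < 0)) {
    abort("`util_means` must be 7 non-negative values.")
  }
  probs <- c(smoker_p = smoker_p, deprived_p = deprived_p, frail_p = frail_p)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (weight < 0) abort("`weight` must be non-negative.")
  if (util_dispersion <= 0) abort("`util_dispersion` must be positive.")
  prev <- setNames(rep(0, length(ltc_conditions())), ltc_conditions())
  if (!is.null(ltc_prevalence)) {
    unknown <- setdiff(names(ltc_prevalence), ltc_conditions())
    if (length(unknown) > 0) {
      abort(paste0("Unknown condition(s): ", paste(unknown, collapse = ", ")))
    }
    if (any(ltc_prevalence < 0 | ltc_prevalence > 1)) {
      abort("LTC prevalences must lie in [0, 1].")
    }
    prev[names(ltc_prevalence)] <- ltc_prevalence
  }
  structure(list(
    weight = weight,
    util_means = setNames(util_means, util),
    util_dispersion = util_dispersion,
    age_mean = age_mean, age_sd = age_sd,
    smoker_p = smoker_p, deprived_p = deprived_p, frail_p = frail_p,
    ltc_prevalence = prev,
    ltc_count_mean = ltc_count_mean,
    risk_mean = risk_mean, risk_sd = risk_sd,
    cost_unit_prices = setNames(as.numeric(cost_unit_prices), util),
    cost_noise_sd = cost_noise_sd,
    bed_days_means = bed_days_means
  ), class = "popseg_segment_spec")
}

# Plausible GBP tariffs per unit of activity; configurable, and deliberately
# not calibrated to reproduce any published per-head cost.
default_unit_prices <- function() {
  c(nonelective_adm = 1800, elective_adm = 1500, op_first = 180,
    op_followup = 120, gp_visits = 35, distinct_drugs = 60,
    ae_attendances = 160)
}

#' Default generator configuration
#'
#' Builds the ten-segment mixture whose weights, utilisation means,
#' demographics, risk scores, long-term-condition prevalences and frailty
#' rates are the reference profiles in [segment_reference_profiles()]
#' (weights are the per-segment population counts divided by 79,607, so the
#' largest, low-utilisation segment holds about half the population and the
#' sickest segments about 1% each).
#'
#' @param n Cohort size to generate.
#' @param seed Integer seed.
#' @param util_dispersion Shared negative-binomial dispersion (default 1).
#' @return A list of class `popseg_generator_config` with elements
#'   `segments`, `n` and `seed`.
#' @export
default_generator_config <- function(n = 79607L, seed = 1L,
                                     util_dispersion = 1) {
  ref <- segment_reference_profiles()
  segs <- purrr::pmap(ref, function(...) {
    r <- list(...)
    prev <- vapply(ltc_conditions(),
                   function(cc) r[[paste0("ltc_", cc, "_pct")]] / 100,
                   numeric(1))
    segment_spec(
      weight = r$n_people / sum(ref$n_people),
      util_means = unlist(r[paste0("util_", utilisation_settings())]),
      util_dispersion = util_dispersion,
      age_mean = r$age_mean, age_sd = r$age_sd,
      smoker_p = r$smoker_pct / 100,
      deprived_p = r$deprived_pct / 100,
      frail_p = r$frail_pct / 100,
      ltc_prevalence = prev,
      ltc_count_mean = r$ltc_count_mean,
      risk_mean = r$risk_mean, risk_sd = r$risk_sd,
      bed_days_means = c(elective = r$bed_days_elective,
                         nonelective = r$bed_days_nonelective,
                         maternity = r$bed_days_maternity)
    )
  })
  generator_config(segments = segs, n = n, seed = seed)
}

#' Assemble a generator configuration
#'
#' @param segments List of [segment_spec()] objects; weights are normalised
#'   to sum to one.
#' @param n Cohort size (at least 1).
#' @param seed Integer seed.
#' @return A list of class `popseg_generator_config`.
#' @export
generator_config <- function(segments, n, seed = 1L) {
  if (n < 1) abort("`n` must be at least 1.")
  if (!length(segments)) abort("At least one segment is required.")
  ok <- vapply(segments, inherits, logical(1), "popseg_segment_spec")
  if (!all(ok)) abort("`segments` must be a list of segment_spec objects.")
  w <- vapply(segments, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) abort("Segment weights must sum to a positive value.")
  for (i in seq_along(segments)) segments[[i]]$weight <- w[i] / sum(w)
  structure(list(segments = segments, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "popseg_generator_config")
}

# Inverse-CDF truncated normal on [lo, hi]; vectorised and seed-stable.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 105) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Beta draw with moments matched to (m, s); clamped to [0, 1].
rbeta_moments <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  v <- s^2
  if (v >= m * (1 - m)) {
    abort(paste0("risk_sd too large for mean ", m,
                 ": need sd^2 < mean * (1 - mean)."))
  }
  nu <- m * (1 - m) / v - 1
  pmin(pmax(rbeta(n, m * nu, (1 - m) * nu), 0), 1)
}

rcount <- function(n, mu, dispersion) {
  if (mu <= 0) return(integer(n))
  rnbinom(n, size = dispersion, mu = mu)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from the segment mixture: each patient first draws a segment
#' label from the weights, then utilisation counts (negative binomial), age
#' (truncated normal), booleans (Bernoulli), total LTC count (negative
#' binomial), risk score (moment-matched beta), bed days and cost (unit
#' prices times counts plus half-normal noise). The true segment label is
#' returned in its own `true_segment` column so recovery tests never feed it
#' to the clustering. Identical configurations (including the seed) give
#' bit-identical cohorts.
#'
#' @param config A `popseg_generator_config`, e.g. from
#'   [default_generator_config()].
#' @return A validated cohort tibble with `true_segment`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "popseg_generator_config")) {
    abort("`config` must be a popseg_generator_config.")
  }
  n <- config$n
  segs <- config$segments
  w <- vapply(segs, `[[`, numeric(1), "weight")
  util <- utilisation_settings()
  withr::with_seed(config$seed, {
    lab <- sample.int(length(segs), n, replace = TRUE, prob = w)
    cols <- list(patient_id = sprintf("P%07d", seq_len(n)))
    util_mat <- matrix(0L, n, 7, dimnames = list(NULL, util))
    age <- numeric(n); smoker <- logical(n); deprived <- logical(n)
    frail <- logical(n); risk <- numeric(n); ltc_count <- integer(n)
    cost <- numeric(n)
    bd <- matrix(0L, n, 3,
                 dimnames = list(NULL, c("elective", "nonelective", "maternity")))
    flags <- matrix(FALSE, n, length(ltc_conditions()),
                    dimnames = list(NULL, ltc_flag_cols()))
    for (s in seq_along(segs)) {
      idx <- which(lab == s)
      if (!length(idx)) next
      sp <- segs[[s]]
      m <- length(idx)
      for (j in seq_along(util)) {
        util_mat[idx, j] <- rcount(m, sp$util_means[j], sp$util_dispersion)
      }
      age[idx] <- rtruncnorm(m, sp$age_mean, sp$age_sd)
      smoker[idx] <- runif(m) < sp$smoker_p
      deprived[idx] <- runif(m) < sp$deprived_p
      frail[idx] <- runif(m) < sp$frail_p
      risk[idx] <- rbeta_moments(m, sp$risk_mean, sp$risk_sd)
      ltc_count[idx] <- rcount(m, sp$ltc_count_mean, sp$util_dispersion)
      for (j in seq_along(ltc_conditions())) {
        flags[idx, j] <- runif(m) < sp$ltc_prevalence[j]
      }
      for (j in 1:3) {
        bd[idx, j] <- rcount(m, sp$bed_days_means[j], sp$util_dispersion)
      }
      cost[idx] <- as.numeric(util_mat[idx, , drop = FALSE] %*%
                                sp$cost_unit_prices) +
        abs(rnorm(m, 0, sp$cost_noise_sd))
    }
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.501, 0.499))
    out <- tibble::as_tibble(util_mat)
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = cols$patient_id), out,
      tibble::tibble(
        age = age, sex = sex, deprived_q12 = deprived, smoker = smoker,
        risk_score = risk, ltc_count = ltc_count,
        frail_mod_severe = frail, cost_gbp = cost,
        bed_days_elective = bd[, 1], bed_days_nonelective = bd[, 2],
        bed_days_maternity = bd[, 3]),
      tibble::as_tibble(flags),
      tibble::tibble(true_segment = lab))
    validate_cohort(out, strict = TRUE)
  })
}

#' Generate a planted-cluster cohort
#'
#' Test harness for the k-selection and k-means machinery: emits `k`
#' spherical Gaussian clusters (unit within-cluster SD) in the 7-dimensional
#' utilisation space, with centroids at least `separation` within-cluster SDs
#' apart, shifted into the positive orthant and rounded to non-negative
#' integer counts. True labels are returned in `true_segment`.
#'
#' @param k Number of planted clusters (at least 2; 1 allowed for null-case
#'   checks).
#' @param n Number of patients.
#' @param separation Minimum centroid spacing in within-cluster SD units.
#' @param seed Integer seed.
#' @return A cohort tibble with `patient_id`, the seven utilisation columns
#'   and `true_segment`.
#' @export
generate_planted_gaussians <- function(k, n, separation = 8, seed = 1L) {
  if (k < 1) abort("`k` must be at least 1.")
  if (separation <= 0) abort("`separation` must be positive.")
  withr::with_seed(as.integer(seed), {
    centroids <- planted_centroids(k, separation)
    lab <- sort(rep_len(seq_len(k), n))
    pts <- matrix(rnorm(n * 7), n, 7) + centroids[lab, , drop = FALSE]
    pts <- pmax(round(pts), 0)
    storage.mode(pts) <- "integer"
    colnames(pts) <- utilisation_settings()
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%07d", seq_len(n))),
      tibble::as_tibble(pts),
      tibble::tibble(true_segment = lab))
    validate_cohort(out, strict = TRUE)
  })
}

# Centroid layout: an isotropic random cloud rescaled so the minimum pairwise
# distance equals `separation`, then shifted so every coordinate is at least
# 4 (the unit noise rarely hits the zero clamp). Spreading the separation
# over all axes keeps the geometry stable under per-axis standardisation,
# which would crush separation concentrated on a single axis. Must be called
# inside the generator's seeded RNG scope.
planted_centroids <- function(k, separation) {
  ctr <- matrix(rnorm(k * 7), k, 7)
  if (k >= 2) {
    dmin <- min(dist(ctr))
    ctr <- ctr * (separation / dmin)
  }
  sweep(ctr, 2, apply(ctr, 2, min), "-") + 4
}
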