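mini_cohort <- function() {
  coh <- tiny_cohort(4)
  coh$age <- c(30, 40, 50, 60)
  coh$cost_gbp <- c(10, 20, 30, 40)
  coh
}

test_that("segment and population means follow hand arithmetic", {
  coh <- mini_cohort()
  prof <- profile_segments(coh, c(1L, 1L, 2L, 2L))
  ages <- dplyr::filter(prof$stats, variable == "age")
  expect_equal(ages$estimate, c(35, 55))
  pop_age <- dplyr::filter(prof$population, variable == "age")
  expect_equal(pop_age$estimate, 45)
  expect_equal(sum(prof$costs$n), prof$n)
})

test_that("a lone segment equals the population row", {
  coh <- mini_cohort()
  prof <- profile_segments(coh, rep(1L, 4))
  seg_stats <- dplyr::select(prof$stats, -"segment")
  expect_equal(as.data.frame(seg_stats), as.data.frame(prof$population))
})

test_that("cost-to-population ratio is cost share over population share", {
  # 100 patients: 1 patient holds 10% of the cost
  coh <- tiny_cohort(100)
  coh$patient_id <- sprintf("P%03d", 1:100)
  coh$cost_gbp <- c(100, rep(900 / 99, 99))
  prof <- profile_segments(coh, c(1L, rep(2L, 99)))
  r <- prof$costs
  expect_equal(r$cost_ratio[r$segment == 1], 0.10 / 0.01)
  expect_equal(sum(r$cost_share), 1)
})

test_that("population means equal population-weighted segment means", {
  coh <- generate_cohort(default_generator_config(n = 3000, seed = 5))
  prof <- profile_segments(coh, coh$true_segment)
  sizes <- prof$costs$n
  for (v in c(utilisation_settings(), "age", "risk_score", "ltc_count")) {
    seg_means <- dplyr::filter(prof$stats, variable == v)$estimate
    pop_mean <- dplyr::filter(prof$population, variable == v)$estimate
    expect_equal(sum(sizes * seg_means) / sum(sizes), pop_mean,
                 tolerance = 1e-9)
  }
})

test_that("empty segments and unassigned patients are rejected", {
  coh <- mini_cohort()
  expect_error(profile_segments(coh, c(1L, 1L, NA, 2L)), "assigned")
  expect_error(profile_segments(coh, c(1L, 1L, 1L)), "one segment per")
})

test_that("each variable family routes to its planned tests", {
  expect_equal(variable_test_plan("gp_visits")$global_test, "kruskal_wallis")
  expect_equal(variable_test_plan("gp_visits")$pairwise_test, "mann_whitney")
  expect_equal(variable_test_plan("ltc_count")$global_test, "kruskal_wallis")
  expect_equal(variable_test_plan("age")$global_test, "anova")
  expect_equal(variable_test_plan("age")$pairwise_test, "t_test")
  expect_equal(variable_test_plan("risk_score")$global_test, "anova")
  expect_equal(variable_test_plan("smoker")$global_test, "chi_square")
  expect_equal(variable_test_plan("smoker")$pairwise_test, "z_test")
  expect_equal(variable_test_plan("ltc_diabetes")$pairwise_test, "z_test")
  expect_error(variable_test_plan("shoe_size"), "shoe_size")
})

test_that("the Bonferroni-adjusted level divides by the k - 1 comparisons", {
  expect_equal(round(bonferroni_alpha(0.05, 10), 4), 0.0056)
  expect_equal(bonferroni_alpha(0.10, 6), 0.02)
  expect_error(bonferroni_alpha(0.05, 1), "k")
})

test_that("identical segments produce a null Kruskal-Wallis statistic", {
  coh <- tiny_cohort(6)
  coh$patient_id <- sprintf("P%03d", 1:6)
  vals <- c(3L, 5L, 9L)
  coh$gp_visits <- c(vals, vals)  # identical multisets in both segments
  tb <- run_test_battery(coh, rep(1:2, each = 3), variables = "gp_visits")
  expect_equal(tb$global$statistic, 0)
  expect_false(any(tb$pairwise$significant))
})

test_that("pooled two-proportion z matches hand arithmetic and chi-square", {
  x1 <- 20; n1 <- 100; x2 <- 40; n2 <- 100
  p_pool <- (x1 + x2) / (n1 + n2)
  z_hand <- (x1 / n1 - x2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  smoker <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 40), rep(FALSE, 60))
  df <- tiny_cohort(200)
  df$patient_id <- sprintf("P%03d", 1:200)
  df$smoker <- smoker
  seg <- rep(1:2, each = 100)
  tb <- run_test_battery(df, seg, variables = "smoker")
  expect_equal(tb$pairwise$statistic, z_hand, tolerance = 1e-12)
  chi <- suppressWarnings(chisq.test(table(seg, smoker), correct = FALSE))
  expect_equal(tb$pairwise$statistic^2, unname(chi$statistic),
               tolerance = 1e-12)
  expect_equal(tb$global$statistic, unname(chi$statistic), tolerance = 1e-12)
})

test_that("pairwise matrices are symmetric with NA diagonals", {
  coh <- generate_cohort(default_generator_config(n = 800, seed = 3))
  tb <- run_test_battery(coh, coh$true_segment,
                         variables = c("gp_visits", "age", "smoker"))
  for (v in c("gp_visits", "age", "smoker")) {
    m <- pairwise_p_matrix(tb, v)
    expect_true(isSymmetric(m))
    expect_true(all(is.na(diag(m))))
  }
})

test_that("pairwise p-values do not depend on segment order", {
  set.seed(44)
  xa <- rnorm(30); xb <- rnorm(25, 0.5)
  for (test in c("mann_whitney", "t_test", "t_test_pooled")) {
    p_ab <- popsegment:::pairwise_stat(test, xa, xb)[["p_value"]]
    p_ba <- popsegment:::pairwise_stat(test, xb, xa)[["p_value"]]
    expect_equal(p_ab, p_ba, tolerance = 1e-12)
  }
  za <- rbinom(40, 1, 0.3); zb <- rbinom(35, 1, 0.6)
  expect_equal(popsegment:::pairwise_stat("z_test", za, zb)[["p_value"]],
               popsegment:::pairwise_stat("z_test", zb, za)[["p_value"]],
               tolerance = 1e-12)
})

test_that("differs-from counts and annotation tiers are consistent", {
  coh <- generate_planted_gaussians(3, 900, separation = 10, seed = 15)
  tb <- run_test_battery(coh, coh$true_segment, variables = "gp_visits")
  ann <- tb$annotations
  expect_true(all(ann$differs_from <= tb$k - 1))
  well_sep <- ann$differs_from == tb$k - 1
  expect_equal(ann$tier[well_sep], rep("x", sum(well_sep)))
})

test_that("segments too small for a continuous test are reported missing", {
  coh <- mini_cohort()
  tb <- run_test_battery(coh, c(1L, 1L, 1L, 2L), variables = "age")
  expect_true(is.na(tb$pairwise$p_value))
  expect_false(tb$pairwise$significant)
})

test_that("null cohorts keep the familywise pairwise error within alpha", {
  # all segments drawn from one distribution; a family is the k - 1
  # comparisons of one segment for one variable; Bonferroni bounds the
  # chance any fires at alpha
  set.seed(1234)
  k <- 5
  n_per <- 30
  n_sims <- 500
  alpha <- 0.05
  alpha_adj <- bonferroni_alpha(alpha, k)
  seg <- rep(seq_len(k), each = n_per)
  pairs <- utils::combn(k, 2)
  fam_hits <- 0
  for (s in seq_len(n_sims)) {
    x <- rnbinom(k * n_per, size = 1, mu = 4)
    sig <- matrix(FALSE, k, k)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      p <- popsegment:::pairwise_stat(
        "mann_whitney", x[seg == a], x[seg == b])[["p_value"]]
      hit <- !is.na(p) && p < alpha_adj
      sig[a, b] <- sig[b, a] <- hit
    }
    fam_hits <- fam_hits + sum(rowSums(sig) > 0)
  }
  n_families <- n_sims * k
  rate <- fam_hits / n_families
  mc_slack <- 3 * sqrt(alpha * (1 - alpha) / n_families)
  expect_lte(rate, alpha + mc_slack)
})
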