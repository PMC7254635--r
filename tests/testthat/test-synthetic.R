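test_that("default generator mirrors the reference segment profiles", {
  cfg <- default_generator_config(n = 100)
  expect_length(cfg$segments, 10)
  w <- vapply(cfg$segments, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1)
  expect_equal(w[1], 39821 / 79607, tolerance = 1e-12)
  # highest-A&E segment carries the reference A&E mean
  ae <- vapply(cfg$segments, function(s) s$util_means[["ae_attendances"]],
               numeric(1))
  expect_equal(max(ae), 5.13)
  expect_equal(cfg$segments[[which.max(ae)]]$util_means[["gp_visits"]], 4.94)
})

test_that("reference profiles are internally consistent", {
  ref <- segment_reference_profiles()
  expect_equal(sum(ref$n_people), 79607)
  expect_equal(nrow(ref), 10)
  expect_equal(sum(ref$characterisation == "High Need, High Complex"), 3)
})

test_that("single-segment counts match their target mean within Monte-Carlo error", {
  spec <- segment_spec(weight = 1,
                       util_means = c(0.14, 0.08, 0.34, 0.91, 0.74, 4.75, 0.41))
  coh <- generate_cohort(generator_config(list(spec), n = 20000, seed = 9))
  m <- 4.75
  v <- m + m^2 / 1  # negative binomial, dispersion 1
  se <- sqrt(v / 20000)
  expect_lt(abs(mean(coh$distinct_drugs) - m), 3 * se)
})

test_that("a zero utilisation mean degenerates to all-zero counts", {
  spec <- segment_spec(weight = 1, util_means = c(0, 0, 0, 0, 0, 5, 0))
  coh <- generate_cohort(generator_config(list(spec), n = 500, seed = 1))
  expect_true(all(coh$elective_adm == 0))
  expect_true(all(coh$nonelective_adm == 0))
  expect_gt(mean(coh$distinct_drugs), 0)
})

test_that("identical seeds reproduce the cohort bit for bit; seeds differ otherwise", {
  cfg <- default_generator_config(n = 400, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg2 <- default_generator_config(n = 400, seed = 8)
  c <- generate_cohort(cfg2)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("cohort-level means obey the law of total expectation", {
  cfg <- default_generator_config(n = 50000, seed = 13)
  coh <- generate_cohort(cfg)
  w <- vapply(cfg$segments, `[[`, numeric(1), "weight")
  for (v in utilisation_settings()) {
    mu_s <- vapply(cfg$segments, function(s) s$util_means[[v]], numeric(1))
    mix_mean <- sum(w * mu_s)
    # mixture variance: E[var|seg] + var of segment means
    var_s <- mu_s + mu_s^2   # nbinom, dispersion 1
    mix_var <- sum(w * (var_s + mu_s^2)) - mix_mean^2
    se <- sqrt(mix_var / 50000)
    expect_lt(abs(mean(coh[[v]]) - mix_mean), 3 * se)
  }
})

test_that("empirical segment shares fall within binomial 3-sigma of the weights", {
  cfg <- default_generator_config(n = 50000, seed = 13)
  coh <- generate_cohort(cfg)
  w <- vapply(cfg$segments, `[[`, numeric(1), "weight")
  shares <- tabulate(coh$true_segment, nbins = 10) / nrow(coh)
  sig <- sqrt(w * (1 - w) / nrow(coh))
  # 10 simultaneous comparisons: Bonferroni-adjust the 3-sigma level
  z_crit <- qnorm(1 - (2 * pnorm(-3)) / 2 / 10)
  expect_true(all(abs(shares - w) < z_crit * sig + 1e-12))
})

test_that("infeasible risk-score moments are rejected", {
  expect_error(
    generate_cohort(generator_config(
      list(segment_spec(weight = 1, util_means = rep(1, 7),
                        risk_mean = 0.05, risk_sd = 0.4)),
      n = 10, seed = 1)),
    "risk_sd")
})

test_that("planted Gaussians are recoverable and carry truth labels apart", {
  coh <- generate_planted_gaussians(k = 2, n = 200, separation = 10, seed = 21)
  expect_setequal(names(coh),
                  c("patient_id", utilisation_settings(), "true_segment"))
  fit <- segment_cohort(coh, k = 2)
  expect_equal(adjusted_rand(fit$assignment$segment, coh$true_segment), 1)
})

test_that("a single planted cluster yields a valid null Duda-Hart record", {
  coh <- generate_planted_gaussians(k = 1, n = 150, separation = 5, seed = 2)
  z <- standardize_utilisation(coh)
  tree <- build_tree(z)
  rec <- duda_hart(tree, 1)
  expect_gt(rec$dh_index, 0)
  expect_lte(rec$dh_index, 1)
  expect_true(is.finite(rec$pseudo_t2))
})
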