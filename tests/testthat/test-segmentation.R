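make_util_tbl <- function(m) {
  colnames(m) <- utilisation_settings()
  tibble::as_tibble(m)
}

test_that("standardiser uses sample moments and rejects zero variance", {
  coh <- make_util_tbl(matrix(rep(c(0, 1, 2), 7), 3, 7))
  std <- fit_standardizer(coh)
  expect_equal(unname(std$mu), rep(1, 7))
  expect_equal(unname(std$sigma), rep(1, 7))   # sample SD, denominator n - 1

  coh2 <- coh
  coh2$distinct_drugs <- rep(4.75, 3)
  expect_error(fit_standardizer(coh2), "distinct_drugs")
})

test_that("standardisation is exact, invertible and centred on the fit data", {
  set.seed(1)
  coh <- make_util_tbl(matrix(rpois(70 * 7, 3) + rep(0:6, each = 70), 70, 7))
  std <- fit_standardizer(coh)
  z <- standardize_utilisation(coh, std)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # x = mu maps to 0, x = mu + sigma maps to 1
  at_mu <- make_util_tbl(matrix(std$mu, 1, 7, byrow = TRUE))
  expect_equal(unname(standardize_utilisation(at_mu, std)[1, ]), rep(0, 7))
  at_mu_sig <- make_util_tbl(matrix(std$mu + std$sigma, 1, 7, byrow = TRUE))
  expect_equal(unname(standardize_utilisation(at_mu_sig, std)[1, ]), rep(1, 7))
  back <- unstandardize_utilisation(z, std)
  expect_lt(max(abs(back - as.matrix(coh))), 1e-12)
})

test_that("scaling a raw column by a positive constant leaves z-scores unchanged", {
  set.seed(2)
  coh <- make_util_tbl(matrix(rpois(50 * 7, 4), 50, 7))
  z1 <- standardize_utilisation(coh)
  coh2 <- coh
  coh2$gp_visits <- coh2$gp_visits * 1000
  z2 <- standardize_utilisation(coh2)
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("ward tree merges nearest points first and cuts cleanly", {
  pts <- matrix(c(0, 1, 10), 3, 1)
  tree <- build_tree(pts, "ward")
  lab2 <- cut_tree(tree, 2)
  expect_equal(lab2[1], lab2[2])   # {0,1} merged before 10 joins
  expect_false(lab2[1] == lab2[3])

  # identical points merge at height zero
  tree0 <- build_tree(matrix(c(5, 5, 9), 3, 1))
  expect_equal(min(tree0$hclust$height), 0)

  # n singletons have zero within-SS; with B > 0 the pseudo-F is infinite
  labs <- cut_tree(tree, 3)
  expect_equal(length(unique(labs)), 3)
  expect_equal(oracle_within_ss(pts, labs), 0)
  pts4 <- matrix(c(0, 1, 10, 11), 4, 1)
  tree4 <- build_tree(pts4, "ward")
  expect_equal(ch_pseudo_f(matrix(c(0, 0, 10, 10), 4, 1), c(1, 1, 2, 2)), Inf)
  expect_equal(length(unique(cut_tree(tree4, 4))), 4)
})

test_that("pseudo-F matches the hand-computed worked example", {
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(ch_pseudo_f(pts, c(1, 1, 2, 2)), 200)  # W=1, B=100
  expect_equal(ch_pseudo_f(matrix(rep(3, 4), 4, 1), c(1, 1, 2, 2)), 0)
  expect_error(ch_pseudo_f(pts, c(1, 1, 1, 1)), "2 <= k")
})

test_that("pseudo-F agrees with a brute-force SS oracle on random instances", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(6:30, 1)
    k <- sample(2:5, 1)
    inst <- random_instance(n, k)
    expect_equal(ch_pseudo_f(inst$points, inst$labels),
                 oracle_pseudo_f(inst$points, inst$labels),
                 tolerance = 1e-9)
  }
})

test_that("between plus within equals total sum of squares", {
  set.seed(7)
  for (rep in 1:25) {
    inst <- random_instance(sample(8:25, 1), sample(2:4, 1))
    n <- nrow(inst$points)
    k <- length(unique(inst$labels))
    w <- oracle_within_ss(inst$points, inst$labels)
    tss <- oracle_total_ss(inst$points)
    f <- ch_pseudo_f(inst$points, inst$labels)
    # reconstruct B from the implementation's F and compare to TSS - W
    b <- f * (k - 1) * w / (n - k)
    expect_equal(b + w, tss, tolerance = 1e-9 * tss)
  }
})

test_that("Duda-Hart matches the worked example and its algebraic identity", {
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  tree <- build_tree(pts, "ward")
  rec <- duda_hart(tree, 1)
  expect_equal(rec$je1, 101)
  expect_equal(rec$je2, 1)
  expect_equal(rec$dh_index, 1 / 101)
  expect_equal(rec$pseudo_t2, 200)
  expect_equal(rec$dh_index, 1 / (1 + rec$pseudo_t2 / (rec$n1 + rec$n2 - 2)))
})

test_that("the Duda-Hart/pseudo-T2 identity holds on every split of random trees", {
  set.seed(11)
  for (rep in 1:10) {
    pts <- matrix(rnorm(20 * 3), 20, 3)
    tree <- build_tree(pts)
    for (g in 1:15) {
      rec <- duda_hart(tree, g)
      if (rec$n1 + rec$n2 > 2 && rec$je2 > 0 && rec$je1 > 0) {
        expect_equal(rec$dh_index,
                     1 / (1 + rec$pseudo_t2 / (rec$n1 + rec$n2 - 2)),
                     tolerance = 1e-9)
      }
      expect_gte(rec$dh_index, 0)
      expect_lte(rec$dh_index, 1 + 1e-12)
    }
  }
})

test_that("splitting a cluster of two identical pairs gives dh 0 and infinite T2", {
  pts <- matrix(c(0, 0, 10, 10), 4, 1)
  tree <- build_tree(pts, "ward")
  rec <- duda_hart(tree, 1)
  expect_equal(rec$dh_index, 0)
  expect_equal(rec$pseudo_t2, Inf)
})

test_that("k-means closed forms: k = 1 grand mean; the 4-point worked example", {
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  fit1 <- kmeans_fit(pts, 1, restarts = 2, seed = 1)
  expect_equal(as.vector(fit1$centroids), 5.5)
  expect_equal(fit1$objective, oracle_total_ss(pts))

  fit2 <- kmeans_fit(pts, 2, restarts = 5, seed = 1)
  expect_equal(fit2$objective, 1.0)
  expect_equal(fit2$assignment[1], fit2$assignment[2])
  expect_equal(fit2$assignment[3], fit2$assignment[4])
  expect_error(kmeans_fit(matrix(c(1, 1, 1), 3, 1), 2), "distinct")
})

test_that("the Lloyd objective trace is non-increasing", {
  set.seed(5)
  for (rep in 1:10) {
    pts <- matrix(rnorm(60 * 4), 60, 4)
    fit <- kmeans_fit(pts, 4, restarts = 1, seed = rep)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("k-means attains the exhaustive optimum on tiny instances", {
  set.seed(99)
  hits <- 0
  for (rep in 1:100) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    fit <- kmeans_fit(pts, k, restarts = 10, seed = rep)
    best <- oracle_kmeans_optimum(pts, k)
    if (fit$objective <= best * (1 + 1e-8)) hits <- hits + 1
    expect_gte(fit$objective, best * (1 - 1e-8))
  }
  expect_gte(hits, 95)
})

test_that("k-means agrees with the stats reference on a moderate instance", {
  coh <- generate_planted_gaussians(5, 1000, separation = 6, seed = 77)
  z <- standardize_utilisation(coh)
  ours <- kmeans_fit(z, 5, restarts = 10, seed = 3)
  ref <- stats::kmeans(z, 5, nstart = 25, iter.max = 100,
                       algorithm = "Lloyd")
  expect_equal(ours$objective, ref$tot.withinss, tolerance = 1e-6)
})

test_that("every point ends assigned to its nearest centroid", {
  set.seed(8)
  pts <- matrix(rnorm(80 * 3), 80, 3)
  fit <- kmeans_fit(pts, 5, restarts = 3, seed = 2)
  d2 <- as.matrix(dist(rbind(fit$centroids, pts)))[-(1:5), 1:5]^2
  nearest <- apply(d2, 1, which.min)
  expect_equal(d2[cbind(seq_len(80), fit$assignment)],
               d2[cbind(seq_len(80), nearest)], tolerance = 1e-9)
})

test_that("relabelling by size is deterministic, stable and idempotent", {
  fit <- structure(list(
    k = 3L, centroids = matrix(1:3, 3, 1), assignment = c(1L, 2L, 2L, 3L),
    sizes = c(1L, 2L, 1L), objective = 0, objective_trace = 0,
    iterations = 1L, converged = TRUE), class = "popseg_kmeans")
  rel <- relabel_by_size(fit)
  # old-2 (size 2) -> 1; ties (old-1, old-3, size 1) by ascending old id
  expect_equal(rel$assignment, c(2L, 1L, 1L, 3L))
  expect_equal(rel$sizes, c(2L, 1L, 1L))
  expect_equal(as.vector(rel$centroids), c(2, 1, 3))
  again <- relabel_by_size(rel)
  expect_identical(again$assignment, rel$assignment)
  expect_identical(again$centroids, rel$centroids)
})

test_that("planted partitions are recovered almost perfectly at separation 6", {
  for (seed in 1:3) {
    coh <- generate_planted_gaussians(4, 800, separation = 6, seed = seed)
    fit <- segment_cohort(coh, k = 4)
    expect_gt(adjusted_rand(fit$assignment$segment, coh$true_segment), 0.9)
  }
})

test_that("consensus selection recovers small planted cluster counts", {
  coh <- generate_planted_gaussians(3, 600, separation = 8, seed = 5)
  ks <- select_k(coh, popseg_config(n_subsets = 5, subset_size = 200,
                                    k_range = c(2L, 8L), seed = 11))
  expect_equal(ks$k, 3)

  coh2 <- generate_planted_gaussians(2, 400, separation = 12, seed = 3)
  ks2 <- select_k(coh2, popseg_config(n_subsets = 5, subset_size = 150,
                                      k_range = c(2L, 6L), seed = 4))
  expect_equal(ks2$k, 2)
  expect_true(all(ks2$suggestions$suggested_k == 2))
})

test_that("selection demands subset_size within the cohort and k in range", {
  coh <- generate_planted_gaussians(2, 100, separation = 8, seed = 1)
  expect_error(select_k(coh, popseg_config(subset_size = 500)),
               "subset_size")
  ks <- select_k(coh, popseg_config(n_subsets = 3, subset_size = 60,
                                    k_range = c(2L, 5L), seed = 9))
  expect_gte(ks$k, 2)
  expect_lte(ks$k, 5)
})

test_that("clustering output is invariant to rescaling a raw column", {
  coh <- generate_planted_gaussians(3, 300, separation = 8, seed = 6)
  fit1 <- segment_cohort(coh, k = 3)
  coh2 <- coh
  coh2$distinct_drugs <- coh2$distinct_drugs * 7L
  fit2 <- segment_cohort(coh2, k = 3)
  expect_equal(adjusted_rand(fit1$assignment$segment,
                             fit2$assignment$segment), 1)
})
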