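# Shared fixtures and independent oracles for the test suite.

# A minimal valid cohort with only the required columns.
tiny_cohort <- function(n = 3) {
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    nonelective_adm = rep_len(c(0L, 1L, 2L), n),
    elective_adm = rep_len(c(1L, 0L, 0L), n),
    op_first = rep_len(c(0L, 2L, 1L), n),
    op_followup = rep_len(c(3L, 0L, 1L), n),
    gp_visits = rep_len(c(2L, 4L, 0L), n),
    distinct_drugs = rep_len(c(5L, 1L, 3L), n),
    ae_attendances = rep_len(c(0L, 1L, 0L), n)
  )
}

# Brute-force sum-of-squares oracle, written as plain loops so it shares no
# code with the implementation under test.
oracle_within_ss <- function(points, labels) {
  points <- as.matrix(points)
  total <- 0
  for (g in unique(labels)) {
    rows <- which(labels == g)
    ctr <- colMeans(points[rows, , drop = FALSE])
    for (i in rows) total <- total + sum((points[i, ] - ctr)^2)
  }
  total
}

oracle_total_ss <- function(points) {
  oracle_within_ss(points, rep(1, nrow(as.matrix(points))))
}

oracle_pseudo_f <- function(points, labels) {
  n <- nrow(as.matrix(points))
  k <- length(unique(labels))
  w <- oracle_within_ss(points, labels)
  b <- oracle_total_ss(points) - w
  (b / (k - 1)) / (w / (n - k))
}

# Exhaustive k-means optimum: enumerate every assignment of n points to k
# clusters (labels up to permutation) and take the minimal objective over
# assignments using all k clusters.
oracle_kmeans_optimum <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n <= 10)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    lab <- grid[i, ]
    if (length(unique(lab)) < k) next
    best <- min(best, oracle_within_ss(points, lab))
  }
  best
}

# Chance-corrected pairwise agreement between two partitions (adjusted Rand).
adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Random small labelled instance for property loops.
random_instance <- function(n, k, d = 3) {
  pts <- matrix(rnorm(n * d), n, d)
  lab <- sample(rep_len(seq_len(k), n))
  list(points = pts, labels = lab)
}
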