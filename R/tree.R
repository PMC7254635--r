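#' Build an agglomerative clustering tree
#'
#' Hierarchical clustering of standardised utilisation points under Ward's
#' criterion (default; each merge minimises the increase in total
#' within-group sum of squares, the quantity both stopping indices are built
#' from) or average/complete linkage. The returned object keeps the point
#' matrix so within-group sums of squares can be evaluated at any cut.
#'
#' @param points Numeric matrix of points (rows) to cluster, typically from
#'   [standardize_utilisation()].
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return An object of class `popseg_tree` wrapping the `stats::hclust`
#'   merge history and the points.
#' @export
build_tree <- function(points, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  points <- as.matrix(points)
  if (nrow(points) < 2) abort("At least 2 points are required.")
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  hc <- hclust(dist(points), method = method)
  structure(list(hclust = hc, points = points, linkage = linkage,
                 n = nrow(points)),
            class = "popseg_tree")
}

#' Cut a tree into g groups
#'
#' @param tree A `popseg_tree`.
#' @param g Number of groups (1 to n).
#' @return Integer membership vector of length n.
#' @export
cut_tree <- function(tree, g) {
  stopifnot(inherits(tree, "popseg_tree"))
  cutree(tree$hclust, k = g)
}

# Within-group sum of squared Euclidean distances to group means.
# Returns a named vector, one entry per group.
group_within_ss <- function(points, labels) {
  labels <- as.integer(factor(labels))
  ctr <- rowsum(points, labels) / as.vector(table(labels))
  ss_point <- rowSums((points - ctr[labels, , drop = FALSE])^2)
  as.vector(rowsum(ss_point, labels))
}

total_within_ss <- function(points, labels) sum(group_within_ss(points, labels))

#' Duda-Hart split diagnostics at a cut
#'
#' Moving from `g` to `g + 1` groups splits exactly one cluster of the cut
#' into two children. The index compares the parent's within-cluster sum of
#' squared distances from its mean, Je(1), to the children's summed
#' within-SS, Je(2): `dh_index = Je(2)/Je(1)` (near 1 when the split adds
#' little) and `pseudo_t2 = (Je(1) - Je(2)) / (Je(2) / (n1 + n2 - 2))`. The
#' two satisfy `dh_index = 1 / (1 + pseudo_t2 / (n1 + n2 - 2))`. Je(1) = 0
#' leaves the index undefined (`NA`); Je(2) = 0 with Je(1) > 0 gives
#' `dh_index = 0` and an infinite pseudo-T^2.
#'
#' @param tree A `popseg_tree`.
#' @param g Number of groups before the split (1 to n - 1).
#' @return A one-row tibble: `g`, `je1`, `je2`, `dh_index`, `pseudo_t2`,
#'   `n1`, `n2`.
#' @export
duda_hart <- function(tree, g) {
  stopifnot(inherits(tree, "popseg_tree"))
  if (g < 1 || g >= tree$n) abort("`g` must lie in [1, n - 1].")
  lab_g <- cut_tree(tree, g)
  lab_g1 <- cut_tree(tree, g + 1)
  tab <- table(lab_g, lab_g1)
  parent <- which(rowSums(tab > 0) == 2)
  if (length(parent) != 1) abort("Cut does not split exactly one cluster.")
  parent_id <- as.integer(rownames(tab)[parent])
  child_ids <- as.integer(colnames(tab)[tab[parent, ] > 0])
  idx <- lab_g == parent_id
  pts <- tree$points[idx, , drop = FALSE]
  kid <- lab_g1[idx]
  je1 <- total_within_ss(pts, rep(1L, nrow(pts)))
  je2 <- total_within_ss(pts, kid)
  n1 <- sum(kid == child_ids[1])
  n2 <- sum(kid == child_ids[2])
  dh <- if (je1 > 0) je2 / je1 else NA_real_
  t2 <- if (n1 + n2 <= 2) {
    NA_real_
  } else if (je2 > 0) {
    (je1 - je2) / (je2 / (n1 + n2 - 2))
  } else if (je1 > 0) {
    Inf
  } else {
    NA_real_
  }
  tibble::tibble(g = as.integer(g), je1 = je1, je2 = je2, dh_index = dh,
                 pseudo_t2 = t2, n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Calinski-Harabasz pseudo-F
#'
#' Compares the mean between-group sum of squares to the mean within-group
#' sum of squares for a partition into k groups of n points:
#' `[B / (k - 1)] / [W / (n - k)]`, where W sums squared distances to group
#' means and B sums group sizes times squared distances of group means from
#' the grand mean; B + W equals the total sum of squares about the grand
#' mean. Larger values indicate tighter, better-separated clusters.
#'
#' @param points Numeric matrix of points.
#' @param labels Group membership (2 <= k <= n - 1 non-empty groups).
#' @return The pseudo-F value; `Inf` when W = 0 with B > 0; 0 when B = 0.
#' @export
ch_pseudo_f <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (length(labels) != n) abort("`labels` must match the number of points.")
  if (anyNA(labels)) abort("`labels` must not contain missing values.")
  f <- factor(labels)
  if (any(table(f) == 0)) abort("Empty group in `labels`.")
  k <- nlevels(f)
  if (k < 2 || k > n - 1) abort("pseudo-F requires 2 <= k <= n - 1 groups.")
  w <- total_within_ss(points, f)
  tss <- total_within_ss(points, rep(1L, n))
  b <- tss - w
  if (w <= 0) {
    if (b <= 0) return(0)
    return(Inf)
  }
  if (b <= 0) return(0)
  (b / (k - 1)) / (w / (n - k))
}
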