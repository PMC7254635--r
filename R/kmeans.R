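#' Fit k-means on standardised utilisation points
#'
#' Lloyd's algorithm with squared Euclidean distance: assign every point to
#' its nearest centroid (ties to the lowest centroid index), recompute each
#' centroid as the mean of its assigned points, and iterate until the
#' relative decrease of the objective (total within-cluster sum of squares)
#' falls below `tol` or `max_iter` is reached. A cluster emptied during
#' iteration is re-seeded with the point currently farthest from its
#' centroid. `restarts` seeded initialisations (k-means++ by default) are
#' run and the solution with the lowest objective kept.
#'
#' @param points Numeric matrix (n x p) of points, typically z-scored
#'   utilisation counts.
#' @param k Number of clusters (at most the number of distinct points).
#' @param restarts Number of seeded initialisations.
#' @param tol Relative objective-change convergence threshold.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param init `"kmeans++"` or `"random"` (distinct points drawn uniformly).
#' @param seed Integer seed for the initialisations.
#' @return An object of class `popseg_kmeans`: `k`, `centroids` (k x p),
#'   `assignment` (length n, values 1..k), `objective`, `objective_trace`
#'   (per-iteration objective of the winning restart), `iterations`,
#'   `converged`, `sizes`.
#' @export
kmeans_fit <- function(points, k, restarts = 10L, tol = 1e-6,
                       max_iter = 300L, init = c("kmeans++", "random"),
                       seed = 1L) {
  init <- match.arg(init)
  points <- as.matrix(points)
  n <- nrow(points)
  n_distinct <- nrow(unique(points))
  if (k > n_distinct) {
    abort(paste0("k = ", k, " exceeds the number of distinct points (",
                 n_distinct, ")."))
  }
  if (k < 1) abort("`k` must be at least 1.")
  best <- NULL
  for (r in seq_len(restarts)) {
    rseed <- stage_seed(seed, 2) + r
    centres <- withr::with_seed(rseed, init_centroids(points, k, init))
    fit <- lloyd(points, centres, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(c(best, list(k = as.integer(k), restarts = as.integer(restarts),
                         init = init, seed = as.integer(seed))),
            class = "popseg_kmeans")
}

init_centroids <- function(points, k, init) {
  n <- nrow(points)
  if (init == "random") {
    ui <- which(!duplicated(points))
    return(points[sample(ui, k), , drop = FALSE])
  }
  # k-means++: first centre uniform, then proportional to squared distance
  # to the nearest chosen centre.
  centres <- matrix(NA_real_, k, ncol(points))
  centres[1, ] <- points[sample.int(n, 1), ]
  if (k == 1) return(centres)
  d2 <- rowSums(sweep(points, 2, centres[1, ], "-")^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      cand <- which(!duplicated(points) & d2 == 0)
      centres[j, ] <- points[sample(cand, 1), ]
    } else {
      centres[j, ] <- points[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(points, 2, centres[j, ], "-")^2))
  }
  centres
}

# Squared Euclidean distances of every point to every centre (n x k).
dist2_to_centres <- function(points, centres) {
  cross <- points %*% t(centres)
  pmax(outer(rowSums(points^2), rep(1, nrow(centres))) - 2 * cross +
         outer(rep(1, nrow(points)), rowSums(centres^2)), 0)
}

lloyd <- function(points, centres, tol, max_iter) {
  n <- nrow(points)
  k <- nrow(centres)
  obj_trace <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  iter <- 0L
  assign <- rep(1L, n)
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to_centres(points, centres)
    assign <- max.col(-d2, ties.method = "first")
    # Re-seed empty clusters with the point farthest from its centroid.
    empties <- setdiff(seq_len(k), unique(assign))
    if (length(empties) > 0) {
      cur <- d2[cbind(seq_len(n), assign)]
      for (j in empties) {
        far <- which.max(cur)
        centres[j, ] <- points[far, ]
        assign[far] <- j
        cur[far] <- 0
      }
    }
    sizes <- tabulate(assign, nbins = k)
    centres <- rowsum(points, factor(assign, levels = seq_len(k))) /
      pmax(sizes, 1)
    obj <- sum((points - centres[assign, , drop = FALSE])^2)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_prev) &&
        (obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    obj_prev <- obj
  }
  # Final reassignment so every point sits with its nearest centroid.
  d2 <- dist2_to_centres(points, centres)
  assign <- max.col(-d2, ties.method = "first")
  sizes <- tabulate(assign, nbins = k)
  if (all(sizes > 0)) {
    centres <- rowsum(points, factor(assign, levels = seq_len(k))) / sizes
  }
  obj <- sum((points - centres[assign, , drop = FALSE])^2)
  list(centroids = centres, assignment = assign, objective = obj,
       objective_trace = obj_trace, iterations = iter,
       converged = converged, sizes = tabulate(assign, nbins = k))
}

#' Renumber segments by decreasing size
#'
#' Gives deterministic segment ids: 1 is the most populous segment, ties
#' broken by ascending original id. Idempotent.
#'
#' @param model A `popseg_kmeans` fit.
#' @return The model with `assignment`, `centroids` and `sizes` renumbered.
#' @export
relabel_by_size <- function(model) {
  stopifnot(inherits(model, "popseg_kmeans"))
  ord <- order(-model$sizes, seq_along(model$sizes))
  new_id <- integer(model$k)
  new_id[ord] <- seq_len(model$k)
  model$assignment <- new_id[model$assignment]
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$sizes <- model$sizes[ord]
  model
}

#' @export
print.popseg_kmeans <- function(x, ...) {
  cat("<popseg_kmeans> k =", x$k, "\n")
  cat("  objective (total within-SS):", format(x$objective), "\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  iterations:", x$iterations, if (x$converged) "(converged)" else
    "(max_iter reached)", "\n")
  invisible(x)
}

#' @export
tidy.popseg_kmeans <- function(x, ...) {
  ctr <- x$centroids
  colnames(ctr) <- colnames(ctr) %||% paste0("dim", seq_len(ncol(ctr)))
  tibble::as_tibble(ctr) |>
    dplyr::mutate(segment = seq_len(x$k), size = x$sizes, .before = 1) |>
    tidyr::pivot_longer(-c("segment", "size"), names_to = "variable",
                        values_to = "centroid")
}

#' @export
glance.popseg_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$assignment),
                 objective = x$objective, iterations = x$iterations,
                 converged = x$converged, restarts = x$restarts)
}
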