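#' Fit k-means on L2-normalized sentence vectors
#'
#' Lloyd's algorithm on row-normalized vectors, so Euclidean proximity tracks
#' cosine similarity (the quantity the ranking stage uses). Initial centroids
#' are `k` distinct rows drawn with the given seed; any cluster that empties
#' during iteration is re-seeded with the point currently farthest from its
#' centroid, so the fitted model never has empty clusters. The per-sentence
#' cosine distance to the assigned centroid is recorded for pivot selection
#' and intra-cluster ranking.
#'
#' @param X An `embedding_matrix`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed; the fit is deterministic given `(X, k, seed)`.
#' @param max_iter Iteration cap for Lloyd updates.
#' @return An object of class `cluster_model`: `k`, `centroids` (k x d),
#'   `assignment` (named integer vector, sentence_id -> cluster in 1..k),
#'   `distance` (named cosine distances in \[0, 2\]), `inertia` (sum of squared
#'   Euclidean distances on normalized rows), `seed`.
#' @export
fit_kmeans <- function(X, k, seed, max_iter = 100L) {
  stopifnot(inherits(X, "embedding_matrix"))
  V <- X$vectors
  n <- nrow(V)
  if (!all(is.finite(V))) cl_stop("credlift_cluster_error", "non-finite input vectors")
  if (k < 1 || k > n) {
    cl_stop("credlift_cluster_error", "k must be in [1, n]; got k=%d, n=%d", k, n)
  }
  norms <- sqrt(rowSums(V^2))
  if (any(norms == 0)) {
    cl_stop("credlift_cluster_error",
            "zero-norm row(s) cannot be L2-normalized: %s",
            paste(utils::head(X$ids[norms == 0], 5), collapse = ", "))
  }
  U <- V / norms

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  centroids <- kmeanspp_init(U, k)

  assign_vec <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(U, centroids)
    new_assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the globally worst-fit point
    repeat {
      empty <- setdiff(seq_len(k), unique(new_assign))
      if (length(empty) == 0) break
      cur <- d2[cbind(seq_len(n), new_assign)]
      worst <- which.max(cur)
      centroids[empty[1], ] <- U[worst, ]
      d2 <- sq_dist(U, centroids)
      new_assign <- max.col(-d2, ties.method = "first")
    }
    if (iter > 1 && all(new_assign == assign_vec)) break
    assign_vec <- new_assign
    for (j in seq_len(k)) {
      centroids[j, ] <- colMeans(U[assign_vec == j, , drop = FALSE])
    }
  }
  d2 <- sq_dist(U, centroids)
  inertia <- sum(d2[cbind(seq_len(n), assign_vec)])

  cmat <- centroids[assign_vec, , drop = FALSE]
  cosd <- 1 - rowSums(U * cmat) / sqrt(rowSums(cmat^2))
  cosd <- pmin(pmax(cosd, 0), 2)

  structure(
    list(k = as.integer(k), centroids = centroids,
         assignment = stats::setNames(assign_vec, X$ids),
         distance = stats::setNames(cosd, X$ids),
         inertia = inertia, seed = as.integer(seed)),
    class = "cluster_model"
  )
}

# kmeans++ (D^2) seeding: first center uniform, each next drawn with
# probability proportional to the squared distance to the nearest chosen
# center. Far less prone to merging well-separated groups than uniform
# row sampling, while staying deterministic under set.seed().
kmeanspp_init <- function(U, k) {
  n <- nrow(U)
  centers <- matrix(0, nrow = k, ncol = ncol(U))
  centers[1, ] <- U[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- sq_dist(U, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        pick <- sample.int(n, 1)  # all points coincide with a center
      } else {
        pick <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- U[pick, ]
      d2 <- pmin(d2, sq_dist(U, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

sq_dist <- function(U, C) {
  # ||u - c||^2 via the expansion; clamp tiny negatives from cancellation
  d2 <- outer(rowSums(U^2), rowSums(C^2), "+") - 2 * tcrossprod(U, C)
  pmax(d2, 0)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d over %d sentences, inertia=%.4f (seed %d)\n",
              x$k, length(x$assignment), x$inertia, x$seed))
  invisible(x)
}

#' Choose the cluster count with the elbow method
#'
#' Fits k-means for every candidate `k`, then picks the `k` whose
#' (k, inertia) point lies farthest (perpendicular distance, both axes scaled
#' to \[0, 1\]) from the chord joining the curve's endpoints — the sharpest
#' bend of the inertia curve. Ties, including the degenerate exactly-linear
#' curve, resolve toward the smallest `k` (cheaper annotation).
#'
#' @param X An `embedding_matrix`.
#' @param k_range Integer vector of candidate cluster counts (>= 3 values,
#'   all within `[1, n]`).
#' @param seed Seed passed to every [fit_kmeans()] call.
#' @return List with `k` (chosen count) and `table` (tibble of k, inertia,
#'   chord distance) for audit.
#' @export
select_k_elbow <- function(X, k_range, seed) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3) {
    cl_stop("credlift_cluster_error",
            "elbow selection needs at least 3 candidate k values")
  }
  inertia <- vapply(k_range, function(k) fit_kmeans(X, k, seed)$inertia, numeric(1))
  dist <- chord_distances(k_range, inertia)
  best <- which(dist >= max(dist) - 1e-12)[1]
  list(k = k_range[best],
       table = tibble::tibble(k = k_range, inertia = inertia, chord_distance = dist))
}

# Perpendicular distance of each (k, inertia) point from the chord joining
# the curve's endpoints, both axes scaled to [0, 1].
chord_distances <- function(k_range, inertia) {
  xs <- (k_range - k_range[1]) / max(k_range[length(k_range)] - k_range[1], 1)
  span <- max(abs(inertia[1] - inertia[length(inertia)]), .Machine$double.eps)
  ys <- (inertia - inertia[length(inertia)]) / span
  a <- ys[length(ys)] - ys[1]; b <- -1; cc <- ys[1]
  abs(a * xs + b * ys + cc) / sqrt(a^2 + b^2)
}

#' Pivot sentences of each cluster
#'
#' The `m` sentences nearest (cosine) to each cluster centroid — the ones
#' annotated first so the cluster's label distribution can be estimated.
#' Clusters smaller than `m` return all their members. When the total pivot
#' count `k * m` exceeds 15% of the corpus a warning is raised: the initial
#' manual-review budget is meant to stay below that fraction of the batch.
#'
#' @param model A `cluster_model`.
#' @param m Pivots per cluster (>= 1).
#' @param max_pivot_fraction Warning threshold on `k * m / n` (default 0.15).
#' @return Named list (one element per cluster, `"1"` .. `"k"`) of sentence
#'   ids ordered by ascending centroid distance; ties break by sentence id.
#' @export
pivots <- function(model, m, max_pivot_fraction = 0.15) {
  stopifnot(inherits(model, "cluster_model"), m >= 1)
  n <- length(model$assignment)
  if (model$k * m > max_pivot_fraction * n) {
    cl_warn("credlift_pivot_fraction_warning",
            "k * m = %d exceeds %.0f%% of the corpus (n = %d); initial annotation budget is large",
            model$k * m, 100 * max_pivot_fraction, n)
  }
  ids <- names(model$assignment)
  out <- lapply(seq_len(model$k), function(j) {
    member <- ids[model$assignment == j]
    member <- member[order(model$distance[member], member)]
    utils::head(member, m)
  })
  stats::setNames(out, as.character(seq_len(model$k)))
}
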