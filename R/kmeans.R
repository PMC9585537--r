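#' K-means clustering (Lloyd iteration)
#'
#' Implements the classic seven-step K-means procedure: choose k centers at
#' random among the data points, assign every point to its nearest center by
#' Euclidean distance, recompute each center as the mean of its assigned
#' points, and repeat until no point is reassigned. The best of `n_restarts`
#' runs by within-cluster sum of squares (inertia) is returned.
#'
#' When `k` is omitted it defaults to 256 clusters, clamped to `floor(n/2)`
#' (with a warning) when fewer than 512 points are available, since
#' UCI-sized inputs cannot support 256 meaningful clusters.
#'
#' An empty cluster arising during iteration is repaired by re-seeding its
#' center at the point farthest from the stale center.
#'
#' @param points numeric matrix, n x J, all finite.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer RNG seed.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of random restarts; best inertia wins.
#' @param init `"random"` (uniform choice of k distinct points, the default)
#'   or `"kmeans++"` (distance-weighted seeding).
#' @return An object of class `cluster_model`: list with `centroids` (k x J),
#'   `assignments` (1-based cluster index per point), `counts`, `inertia`,
#'   `k`, `n_iter`, and `inertia_trace` (inertia after each assignment pass
#'   of the winning restart).
#' @export
kmeans_fit <- function(points, k = NULL, seed = 1L, max_iter = 100L,
                       n_restarts = 1L, init = c("random", "kmeans++")) {
  init <- match.arg(init)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("points must be finite")
  n <- nrow(points)
  if (is.null(k)) {
    k <- 256L
    if (n < 512L) {
      k <- max(1L, n %/% 2L)
      warning(sprintf("n = %d < 512: clamping default k = 256 to %d", n, k))
    }
  }
  k <- as.integer(k)
  if (k < 1L || k > n) stop(sprintf("k must satisfy 1 <= k <= n (k=%d, n=%d)", k, n))
  stopifnot(max_iter >= 1L, n_restarts >= 1L)

  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- kmeans_once(points, k, max_iter, init)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  best
}

# Squared Euclidean distances between rows of X (n x J) and Z (k x J).
sq_dist <- function(X, Z) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  d2
}

kmeans_once <- function(points, k, max_iter, init) {
  n <- nrow(points)
  Z <- if (init == "random") {
    points[sample(n, k), , drop = FALSE]
  } else {
    kmeanspp_seed(points, k)
  }
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    D2 <- sq_dist(points, Z)
    a <- max.col(-D2, ties.method = "first")
    trace <- c(trace, sum(D2[cbind(seq_len(n), a)]))
    if (identical(a, assign_prev) || it >= max_iter) {
      assign_prev <- a
      break
    }
    assign_prev <- a
    for (c in seq_len(k)) {
      members <- a == c
      if (any(members)) {
        Z[c, ] <- colMeans(points[members, , drop = FALSE])
      } else {
        # re-seed an emptied cluster at the point farthest from its stale center
        far <- which.max(D2[, c])
        Z[c, ] <- points[far, ]
      }
    }
  }
  # final centers = means of the converged assignment
  for (c in seq_len(k)) {
    members <- assign_prev == c
    if (any(members)) Z[c, ] <- colMeans(points[members, , drop = FALSE])
  }
  D2 <- sq_dist(points, Z)
  inertia <- sum(D2[cbind(seq_len(n), assign_prev)])
  structure(
    list(centroids = Z, assignments = assign_prev,
         counts = tabulate(assign_prev, nbins = k),
         inertia = inertia, k = k, n_iter = it,
         inertia_trace = c(trace, inertia)),
    class = "cluster_model"
  )
}

kmeanspp_seed <- function(points, k) {
  n <- nrow(points)
  idx <- sample(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(sq_dist(points, points[idx, , drop = FALSE]), 1L, min)
    d2[idx] <- 0
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- c(idx, sample(n, 1L, prob = p))
  }
  points[idx, , drop = FALSE]
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, inertia = %.6g, %d iterations\n",
              x$k, x$inertia, x$n_iter))
  invisible(x)
}

#' Assign points to the nearest centroid
#'
#' Each point gets the 1-based index of the centroid at the shortest
#' Euclidean distance; ties break to the lowest centroid index.
#'
#' @param points numeric matrix, m x J.
#' @param model a fitted [kmeans_fit()] model.
#' @return integer vector of cluster indices.
#' @export
cluster_assign <- function(points, model) {
  stopifnot(inherits(model, "cluster_model"))
  points <- as.matrix(points)
  if (ncol(points) != ncol(model$centroids)) {
    stop(sprintf("dimension mismatch: points have %d columns, centroids %d",
                 ncol(points), ncol(model$centroids)))
  }
  max.col(-sq_dist(points, model$centroids), ties.method = "first")
}

#' Distance-quantile noise filter
#'
#' Removes the rows whose Euclidean distance to their assigned cluster
#' centroid exceeds the given empirical quantile of all such distances.
#' This is the denoising step the pipeline applies after clustering: rows
#' far from every cluster center are treated as sensor noise.
#'
#' @param t a [feature_table] whose features the model was fitted on.
#' @param model a fitted [kmeans_fit()] model.
#' @param quantile threshold quantile in `(0, 1]`; `1` removes nothing.
#' @param features optional matrix to measure distances in (defaults to
#'   `t$X`); supply the standardized matrix when the model was fitted on
#'   standardized features.
#' @return list with `table` (the filtered [feature_table]), `removed`
#'   (data.frame: `index`, `distance`, `cluster` of each removed row) and
#'   `kept` (indices retained).
#' @export
filter_noise <- function(t, model, quantile = 0.95, features = NULL) {
  stopifnot(inherits(t, "feature_table"), inherits(model, "cluster_model"))
  if (quantile <= 0 || quantile > 1) stop("quantile must lie in (0, 1]")
  X <- if (is.null(features)) t$X else as.matrix(features)
  if (nrow(X) != nrow(t$X)) stop("features rows must match table rows")
  a <- cluster_assign(X, model)
  d <- sqrt(rowSums((X - model$centroids[a, , drop = FALSE])^2))
  thr <- stats::quantile(d, quantile, names = FALSE)
  drop_idx <- which(d > thr)
  keep_idx <- setdiff(seq_len(nrow(X)), drop_idx)
  list(
    table = ft_subset(t, keep_idx),
    removed = data.frame(index = drop_idx, distance = d[drop_idx],
                         cluster = a[drop_idx]),
    kept = keep_idx
  )
}
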