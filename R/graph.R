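#' Weighted graph with Laplacian spectral machinery
#'
#' Wraps a symmetric non-negative weight matrix `W` with zero diagonal,
#' its degree vector `d_i = sum_j W_ij` and the combinatorial Laplacian
#' `L = D - W`. The eigendecomposition `L = X Lambda X^T` is computed
#' lazily by [graph_eigen()] and cached.
#'
#' @param W symmetric non-negative n x n matrix, zero diagonal.
#' @param normalized use the symmetric-normalized Laplacian
#'   `I - D^{-1/2} W D^{-1/2}` instead of `D - W` (off by default).
#' @return An object of class `cardiodx_graph`: list with `W`, `d`, `L`,
#'   `n`, `eig` (NULL until requested).
#' @export
graph_from_weights <- function(W, normalized = FALSE) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  if (any(W < -1e-12)) stop("W must be non-negative")
  if (any(abs(diag(W)) > 1e-12)) stop("W must have a zero diagonal")
  diag(W) <- 0
  d <- rowSums(W)
  L <- if (normalized) {
    s <- 1 / sqrt(pmax(d, .Machine$double.eps))
    diag(n) - (s * W) * rep(s, each = n)
  } else {
    diag(d, nrow = n) - W
  }
  structure(list(W = W, d = d, L = (L + t(L)) / 2, n = n, eig = NULL),
            class = "cardiodx_graph")
}

#' @export
print.cardiodx_graph <- function(x, ...) {
  cat(sprintf("cardiodx_graph: %d nodes, %d edges, total weight %.4g\n",
              x$n, sum(x$W > 0) / 2, sum(x$W) / 2))
  invisible(x)
}

#' Cache the Laplacian eigendecomposition
#'
#' Eigenvalues are returned in ascending order `0 <= lambda_0 <= ...` with
#' an orthonormal eigenvector matrix.
#'
#' @param g a [graph_from_weights()] graph.
#' @return `g` with `$eig = list(vectors, values)` populated.
#' @export
graph_eigen <- function(g) {
  stopifnot(inherits(g, "cardiodx_graph"))
  if (!is.null(g$eig)) return(g)
  eg <- eigen(g$L, symmetric = TRUE)
  ord <- order(eg$values)
  g$eig <- list(vectors = eg$vectors[, ord, drop = FALSE],
                values = pmax(eg$values[ord], 0))
  g
}

#' Patient-similarity k-nearest-neighbour graph
#'
#' Connects each sample to its `k_nn` nearest neighbours (symmetrized by
#' union) with Gaussian weights `w_ij = exp(-||x_i - x_j||^2 / sigma^2)`.
#' `sigma = "auto"` uses the mean distance to the `k_nn`-th neighbour.
#'
#' @param features n x M feature matrix (one row per patient record).
#' @param k_nn number of neighbours, `1 <= k_nn < n`.
#' @param sigma positive bandwidth or `"auto"`.
#' @param normalized passed to [graph_from_weights()].
#' @return A `cardiodx_graph`.
#' @export
build_knn_graph <- function(features, k_nn = 10L, sigma = "auto",
                            normalized = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k_nn >= n) stop(sprintf("k_nn (%d) must be below n (%d)", k_nn, n))
  if (k_nn < 1L) stop("k_nn must be positive")
  D2 <- sq_dist(features, features)
  diag(D2) <- Inf
  nb <- matrix(FALSE, n, n)
  kth <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])[seq_len(k_nn)]
    nb[i, ord] <- TRUE
    kth[i] <- sqrt(D2[i, ord[k_nn]])
  }
  adj <- nb | t(nb) # union symmetrization (max of the two directed masks)
  if (identical(sigma, "auto")) sigma <- mean(kth)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive or 'auto'")
  W <- exp(-D2 / sigma^2) * adj
  diag(W) <- 0
  graph_from_weights(W, normalized = normalized)
}

#' Graph Fourier transform and its inverse
#'
#' Expands a node signal in the Laplacian eigenbasis: `fhat = X^T f`,
#' `f = X fhat`. The transform is orthonormal, so the round trip is exact
#' and energy is preserved (Parseval).
#'
#' @param g a graph (eigendecomposition computed if absent).
#' @param f numeric signal of length n.
#' @param inverse apply the inverse transform.
#' @return transformed signal of length n.
#' @export
graph_fourier <- function(g, f, inverse = FALSE) {
  g <- graph_eigen(g)
  f <- as.numeric(f)
  if (length(f) != g$n) stop("signal length must equal the node count")
  if (inverse) drop(g$eig$vectors %*% f) else drop(crossprod(g$eig$vectors, f))
}

#' Spectral convolution with explicit per-eigenvalue gains
#'
#' `out = X diag(gains) X^T f`: filter a node signal by scaling each graph
#' frequency component. This is the exact (but O(n^3)) route that the
#' polynomial filter [poly_filter()] approximates without any
#' eigendecomposition.
#'
#' @param g a graph.
#' @param f signal of length n.
#' @param gains numeric vector of length n, aligned with ascending
#'   eigenvalues.
#' @return filtered signal.
#' @export
spectral_convolve <- function(g, f, gains) {
  g <- graph_eigen(g)
  if (length(gains) != g$n) stop("gains must have length n")
  if (length(f) != g$n) stop("signal length must equal the node count")
  drop(g$eig$vectors %*% (gains * crossprod(g$eig$vectors, as.numeric(f))))
}

#' Polynomial spectral filter
#'
#' @param theta numeric coefficients `theta_0 .. theta_K`.
#' @return object of class `spectral_filter`.
#' @export
spectral_filter <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) < 1L || !all(is.finite(theta))) {
    stop("theta must be a non-empty finite vector")
  }
  structure(list(theta = theta, K = length(theta) - 1L),
            class = "spectral_filter")
}

#' Apply a polynomial Laplacian filter
#'
#' Computes `sum_k theta_k L^k f` by K repeated matrix-vector products with
#' the Laplacian — never through the eigendecomposition — which makes the
#' filter K-hop localized: the output at a node depends only on nodes within
#' K edges. Equivalent to [spectral_convolve()] with gains
#' `sum_k theta_k lambda^k`.
#'
#' @param g a graph.
#' @param filt a [spectral_filter()] (or bare coefficient vector).
#' @param f signal of length n (or n x c matrix of channel signals).
#' @return filtered signal, same shape as `f`.
#' @export
poly_filter <- function(g, filt, f) {
  stopifnot(inherits(g, "cardiodx_graph"))
  if (!inherits(filt, "spectral_filter")) filt <- spectral_filter(filt)
  vec <- is.null(dim(f))
  Fm <- if (vec) matrix(as.numeric(f), ncol = 1L) else as.matrix(f)
  if (nrow(Fm) != g$n) stop("signal length must equal the node count")
  out <- filt$theta[1L] * Fm
  P <- Fm
  for (k in seq_len(filt$K)) {
    P <- g$L %*% P
    out <- out + filt$theta[k + 1L] * P
  }
  if (vec) drop(out) else out
}

# hard partition as a 1-based assignment vector -> indicator matrix
partition_indicator <- function(partition, g_c = NULL) {
  partition <- as.integer(partition)
  if (any(is.na(partition)) || any(partition < 1L)) {
    stop("every node must carry a positive set index")
  }
  if (is.null(g_c)) g_c <- max(partition)
  Y <- matrix(0, length(partition), g_c)
  Y[cbind(seq_along(partition), partition)] <- 1
  Y
}

#' Cut value of a hard partition
#'
#' `cut(S_k, complement) = sum of edge weights crossing out of S_k`; the
#' multi-set cut is half the sum of the per-set boundary weights, so every
#' crossing edge is counted exactly once.
#'
#' @param g a graph.
#' @param partition integer set index (1-based) per node.
#' @return list with `per_set` boundary weights and `total`.
#' @export
cut_value <- function(g, partition) {
  stopifnot(inherits(g, "cardiodx_graph"))
  if (length(partition) != g$n) stop("partition must assign every node")
  Y <- partition_indicator(partition)
  # boundary of set k: sum_{i in k, j not in k} W_ij
  per_set <- vapply(seq_len(ncol(Y)), function(k) {
    ink <- Y[, k] == 1
    sum(g$W[ink, !ink, drop = FALSE])
  }, numeric(1L))
  list(per_set = per_set, total = sum(per_set) / 2)
}

#' Normalized cut of a hard partition
#'
#' `Ncut = sum_k cut(S_k, complement) / vol(S_k)` with
#' `vol(S_k) = sum of degrees in S_k`. Lies in `[0, g_c]` and is zero iff no
#' edge crosses the partition.
#'
#' @param g a graph.
#' @param partition integer set index (1-based) per node.
#' @return normalized-cut value.
#' @export
ncut_value <- function(g, partition) {
  stopifnot(inherits(g, "cardiodx_graph"))
  cv <- cut_value(g, partition)
  Y <- partition_indicator(partition)
  vol <- drop(crossprod(Y, g$d))
  if (any(vol <= 0)) stop("every set must have positive volume")
  sum(cv$per_set / vol)
}

#' Differentiable min-cut loss for a soft assignment
#'
#' `L_cut = sum_{i>j} [(Y / Gamma)(1-Y)^T]_ij A_ij +
#'  sum_k (colsum_k(Y) - n/g)^2`, where `Gamma` broadcasts the soft cluster
#' volumes `vol_k = sum_i d_i Y_ik` so the first term is the soft analogue
#' of the normalized cut (zero at a hard indicator of a partition with no
#' crossing edges), and the second term rewards balanced clusters (zero when
#' every column of `Y` sums to `n/g`).
#'
#' @param Y n x g_c soft assignment matrix; rows non-negative summing to 1.
#' @param g a graph.
#' @param gradient also return the analytic gradient with respect to `Y`.
#' @return the scalar loss, with attributes `cut_term` and `balance_term`;
#'   if `gradient = TRUE`, a list `(value, grad, cut_term, balance_term)`.
#' @export
mincut_loss <- function(Y, g, gradient = FALSE) {
  stopifnot(inherits(g, "cardiodx_graph"))
  Y <- as.matrix(Y)
  if (nrow(Y) != g$n) stop("Y must have one row per node")
  if (any(Y < -1e-9)) stop("Y must be non-negative")
  if (max(abs(rowSums(Y) - 1)) > 1e-6) stop("rows of Y must sum to 1")
  g_c <- ncol(Y)
  n <- g$n
  eps <- 1e-12
  vol <- drop(crossprod(Y, g$d)) + eps
  Alow <- g$W
  Alow[upper.tri(Alow, diag = TRUE)] <- 0 # strict lower triangle
  # S_k = sum_{i>j} A_ij Y_ik (1 - Y_jk)
  S <- vapply(seq_len(g_c), function(k) {
    drop(crossprod(Y[, k], Alow %*% (1 - Y[, k])))
  }, numeric(1L))
  cut_term <- sum(S / vol)
  cs <- colSums(Y)
  balance_term <- sum((cs - n / g_c)^2)
  val <- cut_term + balance_term
  attr(val, "cut_term") <- cut_term
  attr(val, "balance_term") <- balance_term
  if (!gradient) return(val)
  G <- matrix(0, n, g_c)
  for (k in seq_len(g_c)) {
    G[, k] <- (Alow %*% (1 - Y[, k]) - crossprod(Alow, Y[, k])) / vol[k] -
      g$d * S[k] / vol[k]^2
  }
  G <- G + matrix(2 * (cs - n / g_c), n, g_c, byrow = TRUE)
  list(value = as.numeric(val), grad = G,
       cut_term = cut_term, balance_term = balance_term)
}
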