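# Independent brute-force oracles and fixture builders used across the suite.

# Global K-means optimum by exhaustive enumeration of all k^n assignments
# (empty clusters allowed, equivalent to partitions into <= k sets).
kmeans_oracle <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  codes <- 0:(k^n - 1L)
  A <- vapply(seq_len(n), function(i) (codes %/% k^(i - 1L)) %% k,
              numeric(length(codes)))
  sse <- rep(sum(X^2), length(codes))
  for (c in 0:(k - 1L)) {
    Z <- (A == c) * 1
    cnt <- rowSums(Z)
    Sx <- Z %*% X
    contrib <- rowSums(Sx^2) / pmax(cnt, 1)
    contrib[cnt == 0] <- 0
    sse <- sse - contrib
  }
  min(sse)
}

# nearest-centroid labels by explicit distance table
assign_oracle <- function(X, Z) {
  apply(X, 1L, function(x) {
    d <- sqrt(colSums((t(Z) - x)^2))
    which(d == min(d))[1L]
  })
}

# total crossing weight of a hard partition by an explicit edge loop
cut_oracle <- function(W, part) {
  n <- nrow(W)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && part[i] != part[j]) tot <- tot + W[i, j]
    }
  }
  tot
}

partition_indicator_test <- function(part) {
  Y <- matrix(0, length(part), max(part))
  Y[cbind(seq_along(part), part)] <- 1
  Y
}

ncut_oracle <- function(W, part) {
  d <- rowSums(W)
  sum(vapply(sort(unique(part)), function(k) {
    ink <- part == k
    cutk <- sum(W[ink, !ink, drop = FALSE])
    cutk / sum(d[ink])
  }, numeric(1L)))
}

# random symmetric weighted graph with zero diagonal
rand_graph_W <- function(n, seed, density = 0.6) {
  set.seed(seed)
  W <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < density)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# path graph with unit weights
path_graph_W <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) W[i, i + 1L] <- W[i + 1L, i] <- 1
  W
}

# all set partitions of 1..n into exactly g labelled-canonical sets
# (restricted growth strings), returned as a list of assignment vectors
all_partitions <- function(n, g) {
  out <- list()
  rec <- function(a, mx) {
    i <- length(a) + 1L
    if (i > n) {
      if (mx == g) out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(min(mx + 1L, g))) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# plausible processed-Cleveland-format file (synthetic values, real dialect)
make_uci_fixture <- function(path, n = 303L, seed = 42L, missing_frac = 0.01) {
  set.seed(seed)
  cols <- cbind(
    age = sample(29:77, n, TRUE), sex = sample(0:1, n, TRUE),
    cp = sample(1:4, n, TRUE), trestbps = sample(94:200, n, TRUE),
    chol = sample(126:400, n, TRUE), fbs = sample(0:1, n, TRUE),
    restecg = sample(0:2, n, TRUE), thalach = sample(71:202, n, TRUE),
    exang = sample(0:1, n, TRUE), oldpeak = round(runif(n, 0, 6.2), 1),
    slope = sample(1:3, n, TRUE), ca = sample(0:3, n, TRUE),
    thal = sample(c(3, 6, 7), n, TRUE), num = sample(0:4, n, TRUE)
  )
  chr <- matrix(sprintf("%g", cols), n, ncol(cols))
  # sprinkle '?' over predictors only
  nm <- round(missing_frac * n * 13)
  if (nm > 0) {
    ij <- cbind(sample(n, nm, TRUE), sample(13, nm, TRUE))
    chr[ij] <- "?"
  }
  writeLines(apply(chr, 1L, paste, collapse = ","), path)
  invisible(path)
}

expect_equal_up_to_sign <- function(A, B, tol = 1e-6) {
  A <- as.matrix(A); B <- as.matrix(B)
  expect_equal(dim(A), dim(B))
  for (j in seq_len(ncol(A))) {
    err <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(err, tol)
  }
}
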