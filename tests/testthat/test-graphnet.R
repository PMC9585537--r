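test_that("graph_from_weights validates and builds the Laplacian", {
  W <- rand_graph_W(6, seed = 1)
  g <- graph_from_weights(W)
  expect_equal(rowSums(g$L), rep(0, 6), tolerance = 1e-12)
  expect_equal(g$L, t(g$L))
  g <- graph_eigen(g)
  expect_gte(min(g$eig$values), -1e-10)
  expect_equal(crossprod(g$eig$vectors), diag(6), tolerance = 1e-8)
  expect_true(all(diff(g$eig$values) >= -1e-12))

  expect_error(graph_from_weights(matrix(1:9, 3, 3)), "symmetric")
  Wd <- diag(3); expect_error(graph_from_weights(Wd), "zero diagonal")
  Wn <- matrix(0, 2, 2); Wn[1, 2] <- Wn[2, 1] <- -1
  expect_error(graph_from_weights(Wn), "non-negative")
})

test_that("build_knn_graph connects local neighbourhoods symmetrically", {
  # three equidistant points, k_nn = 2: complete graph with equal weights
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  g <- build_knn_graph(pts, k_nn = 2L)
  off <- g$W[upper.tri(g$W)]
  expect_true(all(off > 0))
  expect_equal(max(off) - min(off), 0, tolerance = 1e-12)
  expect_equal(diag(g$W), rep(0, 3))

  # two tight clusters far apart, k_nn = 1: no inter-cluster weight
  set.seed(2)
  X <- rbind(matrix(rnorm(10, sd = 0.01), 5, 2),
             matrix(rnorm(10, sd = 0.01) + 100, 5, 2))
  g2 <- build_knn_graph(X, k_nn = 1L)
  expect_equal(sum(g2$W[1:5, 6:10]), 0)

  for (s in 1:3) {
    set.seed(s)
    Xr <- matrix(rnorm(20 * 3), 20, 3)
    gr <- build_knn_graph(Xr, k_nn = 4L)
    expect_equal(gr$W, t(gr$W))
    expect_equal(diag(gr$W), rep(0, 20))
  }
  expect_error(build_knn_graph(matrix(0, 3, 2), k_nn = 3L), "below n")
})

test_that("graph Fourier transform is orthonormal", {
  # P3 path graph Laplacian spectrum {0, 1, 3}
  g <- graph_eigen(graph_from_weights(path_graph_W(3)))
  expect_equal(g$eig$values, c(0, 1, 3), tolerance = 1e-10)

  # constant signal concentrates on the zero eigenvalue
  fhat <- graph_fourier(g, rep(1, 3))
  expect_equal(abs(fhat[1]), sqrt(3), tolerance = 1e-10)
  expect_equal(fhat[2:3], rep(0, 2), tolerance = 1e-10)

  set.seed(3)
  g6 <- graph_from_weights(rand_graph_W(6, seed = 3))
  f <- rnorm(6)
  fhat <- graph_fourier(g6, f)
  expect_equal(graph_fourier(g6, fhat, inverse = TRUE), f, tolerance = 1e-8)
  expect_equal(sqrt(sum(fhat^2)), sqrt(sum(f^2)), tolerance = 1e-8) # Parseval
})

test_that("spectral_convolve implements the diagonal-gain identity", {
  g <- graph_eigen(graph_from_weights(rand_graph_W(8, seed = 4)))
  f <- rnorm(8)
  expect_equal(spectral_convolve(g, f, rep(1, 8)), f, tolerance = 1e-10)
  expect_equal(spectral_convolve(g, f, g$eig$values), drop(g$L %*% f),
               tolerance = 1e-8)
  gains <- rnorm(8)
  dense <- g$eig$vectors %*% diag(gains) %*% t(g$eig$vectors) %*% f
  expect_equal(spectral_convolve(g, f, gains), drop(dense), tolerance = 1e-10)
  expect_error(spectral_convolve(g, f, rep(1, 3)), "length")
})

test_that("poly_filter matches the spectral route and never decomposes", {
  g <- graph_from_weights(rand_graph_W(10, seed = 5))
  f <- rnorm(10)
  expect_equal(poly_filter(g, c(1), f), f)
  expect_equal(poly_filter(g, c(0, 1), f), drop(g$L %*% f), tolerance = 1e-12)
  expect_null(g$eig) # poly_filter must not trigger the eigendecomposition

  th <- rnorm(4)
  ge <- graph_eigen(g)
  gains <- vapply(ge$eig$values, function(l) sum(th * l^(0:3)), numeric(1))
  expect_equal(poly_filter(g, th, f), spectral_convolve(ge, f, gains),
               tolerance = 1e-6)
  expect_error(spectral_filter(c(1, NA)), "finite")
})

test_that("poly_filter output is K-hop localized (bitwise)", {
  g <- graph_from_weights(path_graph_W(7))
  set.seed(6)
  f <- rnorm(7)
  K <- 2L
  th <- rnorm(K + 1L)
  base <- poly_filter(g, th, f)
  f2 <- f
  f2[7] <- f2[7] + 100 # node 7 is 6 hops from node 1, > K
  pert <- poly_filter(g, th, f2)
  expect_identical(base[1:4], pert[1:4]) # nodes > K hops away: bit-identical
  expect_false(identical(base[7], pert[7]))
})

test_that("cut_value matches the edge-enumeration oracle", {
  # triangle, one vertex against two: two crossing unit edges
  W3 <- matrix(1, 3, 3); diag(W3) <- 0
  g3 <- graph_from_weights(W3)
  cv <- cut_value(g3, c(1, 2, 2))
  expect_equal(cv$total, 2)
  expect_equal(cv$per_set, c(2, 2))

  # disconnected components split apart: zero cut
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  expect_equal(cut_value(graph_from_weights(W), c(1, 1, 2, 2))$total, 0)

  for (s in 1:5) {
    W8 <- rand_graph_W(8, seed = 100 + s)
    g8 <- graph_from_weights(W8)
    part <- sample(1:3, 8, TRUE)
    part <- match(part, sort(unique(part)))
    cv8 <- cut_value(g8, part)
    expect_equal(cv8$total, cut_oracle(W8, part), tolerance = 1e-12)
    # half-sum identity over per-set boundaries
    expect_equal(cv8$total, sum(cv8$per_set) / 2, tolerance = 1e-12)
  }
  expect_error(cut_value(g3, c(1, 2)), "every node")
})

test_that("ncut_value matches hand and oracle enumeration", {
  W4 <- matrix(1, 4, 4); diag(W4) <- 0 # K4
  g4 <- graph_from_weights(W4)
  expect_equal(ncut_value(g4, c(1, 1, 2, 2)), 4 / 6 + 4 / 6, tolerance = 1e-12)

  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  expect_equal(ncut_value(graph_from_weights(W), c(1, 1, 2, 2)), 0)

  for (s in 1:5) {
    W8 <- rand_graph_W(8, seed = 200 + s, density = 1)
    g8 <- graph_from_weights(W8)
    set.seed(s)
    part <- c(1, 2, sample(1:2, 6, TRUE)) # both sets non-empty
    expect_equal(ncut_value(g8, part), ncut_oracle(W8, part), tolerance = 1e-12)
    expect_lte(ncut_value(g8, part), 2)
  }
})

test_that("mincut_loss vanishes on balanced perfect partitions", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  g <- graph_from_weights(W)
  Y <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  v <- mincut_loss(Y, g)
  expect_equal(as.numeric(v), 0, tolerance = 1e-9)

  # uniform assignment balances the column sums exactly
  Yu <- matrix(0.5, 4, 2)
  expect_equal(attr(mincut_loss(Yu, g), "balance_term"), 0, tolerance = 1e-12)

  expect_error(mincut_loss(rbind(c(0.7, 0.2), c(0.5, 0.5)),
                           graph_from_weights(matrix(0, 2, 2))),
               "sum to 1")
})

test_that("mincut_loss matches term-by-term hand evaluation on a triangle", {
  W3 <- matrix(1, 3, 3); diag(W3) <- 0
  g3 <- graph_from_weights(W3)
  Y <- rbind(c(1, 0), c(0, 1), c(0, 1)) # 1 vs {2,3}
  v <- mincut_loss(Y, g3)
  # cut term: S_1 = 0, S_2 = 2 (edges 2-1 and 3-1 cross), volumes 2 and 4
  expect_equal(attr(v, "cut_term"), 0 / 2 + 2 / 4, tolerance = 1e-9)
  # balance: column sums (1, 2) against n/g = 1.5
  expect_equal(attr(v, "balance_term"), 0.25 + 0.25, tolerance = 1e-12)
  expect_equal(as.numeric(v), 1, tolerance = 1e-9)
})

test_that("mincut cut term grows with crossing weight at equal volumes", {
  # ring 1-2-3-4 with unit weights: all degrees (hence volumes) equal
  W <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    W[e[1], e[2]] <- W[e[2], e[1]] <- 1
  }
  g <- graph_from_weights(W)
  Y_adj <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))   # crossing weight 2
  Y_alt <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))   # crossing weight 4
  expect_lt(attr(mincut_loss(Y_adj, g), "cut_term"),
            attr(mincut_loss(Y_alt, g), "cut_term"))
})

test_that("mincut_loss analytic gradient matches finite differences", {
  set.seed(7)
  W <- rand_graph_W(9, seed = 7)
  g <- graph_from_weights(W)
  Y <- exp(matrix(rnorm(9 * 3), 9, 3))
  Y <- Y / rowSums(Y)
  ml <- mincut_loss(Y, g, gradient = TRUE)
  h <- 1e-6
  for (probe in list(c(2, 1, 2), c(5, 2, 3), c(9, 1, 3))) {
    i <- probe[1]; k1 <- probe[2]; k2 <- probe[3]
    Yp <- Y; Yp[i, k1] <- Yp[i, k1] + h; Yp[i, k2] <- Yp[i, k2] - h
    Ym <- Y; Ym[i, k1] <- Ym[i, k1] - h; Ym[i, k2] <- Ym[i, k2] + h
    num <- (as.numeric(mincut_loss(Yp, g)) - as.numeric(mincut_loss(Ym, g))) / (2 * h)
    expect_equal(ml$grad[i, k1] - ml$grad[i, k2], num, tolerance = 1e-5)
  }
})
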