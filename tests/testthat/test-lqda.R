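test_that("scatter_matrices handles point classes and degenerate input", {
  sm <- scatter_matrices(rbind(c(1, 0), c(-1, 0)), c(0, 1))
  expect_equal(sm$Sb, rbind(c(1, 0), c(0, 0)))
  expect_equal(sm$Sw, matrix(0, 2, 2))

  same <- matrix(1, 4, 2)
  sm2 <- scatter_matrices(same, c(0, 0, 1, 1))
  expect_equal(sm2$Sb, matrix(0, 2, 2))
  expect_equal(sm2$Sw, matrix(0, 2, 2))

  expect_error(scatter_matrices(same, rep(0, 4)), "2 classes")
})

test_that("N*Sb + Sw equals the total scatter", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- sample(0:2, 30, TRUE)
  sm <- scatter_matrices(X, y)
  Xc <- sweep(X, 2L, colMeans(X))
  expect_equal(30 * sm$Sb + sm$Sw, crossprod(Xc), tolerance = 1e-10)
})

test_that("discriminative_basis whitens S_b", {
  # isotropic case: any orthonormal pair scaled by 1/2 whitens 4*I
  U <- discriminative_basis(4 * diag(2), 2)
  expect_equal(crossprod(U, 4 * diag(2) %*% U), diag(2), tolerance = 1e-8)
  expect_equal(sqrt(colSums(U^2)), c(0.5, 0.5), tolerance = 1e-10)

  # C = 2 classes span a rank-1 between-class scatter: M = min(C-1, J) = 1
  set.seed(5)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- rep(0:1, each = 10)
  sm <- scatter_matrices(X, y)
  expect_error(discriminative_basis(sm$Sb, 2), "rank 1")
  U1 <- discriminative_basis(sm$Sb, 1)
  expect_equal(ncol(U1), 1L)

  set.seed(6)
  A <- matrix(rnorm(16), 4, 4)
  S <- crossprod(A)
  U4 <- discriminative_basis(S, 4)
  expect_lt(max(abs(crossprod(U4, S %*% U4) - diag(4))), 1e-8)
})

test_that("gram_matrix satisfies kernel identities", {
  expect_equal(gram_matrix(diag(3), kernel_spec("linear")), diag(3))

  set.seed(7)
  X <- matrix(rnorm(8 * 3), 8, 3)
  Kr <- gram_matrix(X, kernel_spec("rbf", sigma = 1.3))
  expect_equal(diag(Kr), rep(1, 8))
  expect_equal(Kr, t(Kr))
  expect_gt(min(eigen(Kr, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # polynomial degree 2 equals the explicit feature-map inner product
  X2 <- matrix(rnorm(3 * 2), 3, 2)
  phi <- function(x) c(1, sqrt(2) * x, x[1]^2, x[2]^2, sqrt(2) * x[1] * x[2])
  Kexp <- tcrossprod(t(apply(X2, 1L, phi)))
  expect_equal(gram_matrix(X2, kernel_spec("polynomial", degree = 2)), Kexp,
               tolerance = 1e-10)

  expect_error(kernel_spec("rbf", sigma = -1), "sigma")
  expect_error(kernel_spec("polynomial", degree = 0.5), "degree")
})

test_that("linear-kernel KDA reproduces direct LDA projections up to sign", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:50, 1)
    J <- sample(3:6, 1)
    C <- sample(2:4, 1)
    X <- matrix(rnorm(n * J), n, J) +
      outer(sample(0:(C - 1), n, TRUE), rep(2, J))
    y <- integer(n)
    repeat {
      y <- sample(0:(C - 1), n, TRUE)
      if (length(unique(y)) == C && min(table(y)) >= 2) break
    }
    M <- C - 1L
    sm <- scatter_matrices(X, y)
    U <- discriminative_basis(sm$Sb, M)
    direct <- X %*% U
    km <- kda_fit(X, y, kernel_spec("linear"), M = M)
    expect_equal_up_to_sign(direct, kda_project(X, km), tol = 1e-6)
  }
})

test_that("kernel between-class basis has rank C-1 for point classes", {
  X <- rbind(matrix(1, 3, 2), matrix(5, 2, 2))
  y <- c(0, 0, 0, 1, 1)
  K <- gram_matrix(X, kernel_spec("linear"))
  b <- kernel_between_class_basis(K, y, 1)
  expect_length(b$lambda, 1L)
  expect_gt(b$lambda, 0)
  expect_error(kernel_between_class_basis(K, y, 2), "only 1 positive")
})

test_that("duplicating every sample leaves projected class means unchanged", {
  set.seed(8)
  X <- matrix(rnorm(15 * 3), 15, 3)
  y <- rep(0:2, each = 5)
  m1 <- kda_fit(X, y, kernel_spec("linear"), M = 2)
  m2 <- kda_fit(rbind(X, X), c(y, y), kernel_spec("linear"), M = 2)
  expect_equal_up_to_sign(m1$class_means, m2$class_means, tol = 1e-6)
})

test_that("projection is definitionally consistent with stored class means", {
  set.seed(9)
  X <- matrix(rnorm(24 * 4), 24, 4)
  y <- rep(0:1, each = 12)
  m <- kda_fit(X, y, kernel_spec("rbf"))
  P <- kda_project(X, m)
  for (i in seq_along(m$classes)) {
    expect_equal(colMeans(P[y == m$classes[i], , drop = FALSE]),
                 m$class_means[i, ], tolerance = 1e-10)
  }
  # a duplicate of a training sample projects to the stored projection
  expect_equal(kda_project(X[3, , drop = FALSE], m), m$train_proj[3, , drop = FALSE],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("regularized covariance limits are exact", {
  set.seed(10)
  for (s in 1:5) {
    Y <- matrix(rnorm(40 * 3), 40, 3)
    y <- sample(0:1, 40, TRUE)
    classes <- sort(unique(y))

    plain <- regularized_covariance(Y, y, alpha = 0, gamma = 0)
    for (i in seq_along(classes)) {
      Yc <- sweep(Y[y == classes[i], ], 2L, colMeans(Y[y == classes[i], ]))
      expect_equal(plain[[i]], crossprod(Yc) / sum(y == classes[i]),
                   tolerance = 1e-12)
    }

    iso <- regularized_covariance(Y, y, alpha = 0.3, gamma = 1)
    for (S in iso) {
      expect_equal(S, diag(S[1, 1], 3), tolerance = 1e-12)
    }

    # alpha = 1: every class gets the directly pooled matrix
    pooled <- regularized_covariance(Y, y, alpha = 1, gamma = 0)
    Spool <- matrix(0, 3, 3)
    for (cl in classes) {
      Yc <- sweep(Y[y == cl, ], 2L, colMeans(Y[y == cl, ]))
      Spool <- Spool + crossprod(Yc)
    }
    Spool <- Spool / 40
    expect_equal(pooled[[1]], Spool, tolerance = 1e-12)
    expect_equal(pooled[[2]], Spool, tolerance = 1e-12)
  }
  expect_error(regularized_covariance(matrix(0, 4, 2), c(0, 0, 1, 1), 2, 0),
               "alpha")
})

test_that("Sigma_i(alpha, gamma) respects the gamma eigenvalue floor", {
  set.seed(11)
  for (s in 1:5) {
    Y <- matrix(rnorm(30 * 3), 30, 3)
    y <- sample(0:2, 30, TRUE)
    a <- runif(1); gm <- runif(1)
    Sa <- regularized_covariance(Y, y, a, 0)
    Sg <- regularized_covariance(Y, y, a, gm)
    for (i in seq_along(Sg)) {
      floor_i <- (gm / 3) * sum(diag(Sa[[i]]))
      expect_gte(min(eigen(Sg[[i]], symmetric = TRUE, only.values = TRUE)$values),
                 floor_i - 1e-10)
    }
  }
})

test_that("mahalanobis rule follows the quadratic discriminant arithmetic", {
  mdl <- structure(
    list(classes = c(0L, 1L), M = 1L, class_means = rbind(0, 2),
         sigmas = list(matrix(0.25), matrix(4)), priors = c(0.5, 0.5)),
    class = "kda_model"
  )
  out <- mahalanobis_classify(1, mdl)
  # d_0 = 1/0.25 + ln 0.25 = 2.6137; d_1 = 1/4 + ln 4 = 1.6363
  expect_equal(out$d[1, 1], 4 + log(0.25) - 2 * log(0.5))
  expect_equal(out$d[1, 2], 0.25 + log(4) - 2 * log(0.5))
  expect_equal(out$class, 1L) # larger-variance class wins at the midpoint
  expect_equal(out$score, out$d[, 1] - out$d[, 2])

  # query at a class mean with equal covariances and priors -> that class
  mdl$sigmas <- list(matrix(1), matrix(1))
  expect_equal(mahalanobis_classify(0, mdl)$class, 0L)
  expect_equal(mahalanobis_classify(2, mdl)$class, 1L)

  # doubling a prior lowers that class's score by exactly 2 ln 2
  d1 <- mahalanobis_classify(1, mdl)$d
  mdl2 <- mdl; mdl2$priors <- c(1, 0.5)
  d2 <- mahalanobis_classify(1, mdl2)$d
  expect_equal(d1[1, 1] - d2[1, 1], 2 * log(2))
  expect_equal(d1[1, 2], d2[1, 2])

  mdl$sigmas <- list(matrix(0), matrix(1))
  expect_error(mahalanobis_classify(1, mdl), "singular")
})

test_that("alpha=1, gamma=1, equal priors reduces to nearest class mean", {
  for (s in 1:4) {
    set.seed(s)
    X <- matrix(rnorm(40 * 4), 40, 4) + 2 * rep(0:1, each = 20)
    y <- rep(0:1, each = 20)
    m <- kda_fit(X, y, kernel_spec("linear"), alpha = 1, gamma = 1)
    P <- kda_project(X, m)
    pred <- mahalanobis_classify(P, m)$class
    nearest <- m$classes[apply(P, 1L, function(p) {
      which.min(colSums((t(m$class_means) - p)^2))
    })]
    expect_equal(pred, nearest)
  }
})

test_that("training accuracy approaches the Bayes limit on separated Gaussians", {
  fit_acc <- function(sep, seed) {
    sp <- synthetic_spec(n_per_class = c(200L, 200L),
                         means = list(c(sep, 0), c(0, 0)),
                         covariances = list(diag(2), diag(2)),
                         outlier_fraction = 0, seed = seed)
    t <- generate_synthetic(sp)
    m <- kda_fit(t$X, t$y, kernel_spec("rbf"))
    pred <- mahalanobis_classify(kda_project(t$X, m), m)$class
    mean(pred == t$y)
  }
  # at 3 sigma the Bayes accuracy is pnorm(1.5) = 0.933: assert within noise
  # of that limit; at 4 sigma (Bayes 0.977) the 0.95 bar is attainable
  expect_gte(fit_acc(3, 21L), 0.90)
  expect_gte(fit_acc(4, 21L), 0.95)
})

test_that("the trace preset clamps gamma at 1 with a warning", {
  set.seed(12)
  X <- matrix(rnorm(30 * 3), 30, 3) + rep(0:1, each = 15)
  y <- rep(0:1, each = 15)
  expect_warning(m <- kda_fit(X, y, kernel_spec("linear"), reg_preset = TRUE),
                 "clamped")
  expect_equal(m$alpha, 1)
  expect_equal(m$gamma, 1)
})
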