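#' Between- and within-class scatter matrices
#'
#' `S_b = sum_i C_i (mu_i - mu)(mu_i - mu)^T / N` and
#' `S_w = sum_i sum_j (x_ij - mu_i)(x_ij - mu_i)^T`. Their sum relates to the
#' total scatter: `N*S_b + S_w = sum (x - mu)(x - mu)^T`.
#'
#' @param X numeric matrix, n x J.
#' @param y class labels, length n; at least two classes.
#' @return list with symmetric matrices `Sb` and `Sw`.
#' @export
scatter_matrices <- function(X, y) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("scatter matrices require at least 2 classes")
  N <- nrow(X)
  mu <- colMeans(X)
  J <- ncol(X)
  Sb <- matrix(0, J, J)
  Sw <- matrix(0, J, J)
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    Ci <- nrow(Xi)
    mi <- colMeans(Xi)
    dm <- mi - mu
    Sb <- Sb + Ci * tcrossprod(dm)
    Xc <- sweep(Xi, 2L, mi)
    Sw <- Sw + crossprod(Xc)
  }
  Sb <- Sb / N
  list(Sb = (Sb + t(Sb)) / 2, Sw = (Sw + t(Sw)) / 2)
}

#' Whitening basis of the between-class scatter
#'
#' Returns `U = V_b A_b^{-1/2}` built from the M leading eigenpairs of `S_b`,
#' so that `U^T S_b U` is the M x M identity. Columns are ordered by
#' descending eigenvalue; the sign of each column is fixed by making its
#' largest-magnitude component positive.
#'
#' @param Sb symmetric between-class scatter matrix.
#' @param M number of basis vectors; `S_b` must have at least M eigenvalues
#'   above `1e-10`.
#' @return J x M matrix `U` with `attr(U, "eigenvalues")`.
#' @export
discriminative_basis <- function(Sb, M) {
  Sb <- as.matrix(Sb)
  eg <- eigen((Sb + t(Sb)) / 2, symmetric = TRUE)
  pos <- sum(eg$values > 1e-10)
  if (pos < M) {
    stop(sprintf("S_b rank %d is below the requested M = %d", pos, M))
  }
  V <- eg$vectors[, seq_len(M), drop = FALSE]
  V <- fix_signs(V)
  U <- sweep(V, 2L, sqrt(eg$values[seq_len(M)]), "/")
  attr(U, "eigenvalues") <- eg$values[seq_len(M)]
  U
}

# deterministic eigenvector orientation: largest-|component| positive
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Kernel specification
#'
#' @param type `"linear"`, `"rbf"` or `"polynomial"`.
#' @param sigma RBF bandwidth (> 0); `NULL` selects the median pairwise
#'   training distance at fit time. `k(x,z) = exp(-||x-z||^2 / (2 sigma^2))`.
#' @param degree polynomial degree (integer >= 1); `k(x,z) = (x.z + 1)^d`.
#' @return list of class `kernel_spec`.
#' @export
kernel_spec <- function(type = c("linear", "rbf", "polynomial"),
                        sigma = NULL, degree = NULL) {
  type <- match.arg(type)
  if (type == "rbf" && !is.null(sigma) && sigma <= 0) stop("sigma must be > 0")
  if (type == "polynomial") {
    if (is.null(degree)) degree <- 2L
    if (degree < 1 || degree != round(degree)) stop("degree must be an integer >= 1")
  }
  structure(list(type = type, sigma = sigma, degree = degree),
            class = "kernel_spec")
}

# kernel evaluations between rows of X (n) and rows of Z (m): n x m matrix
kernel_cross <- function(X, Z, kernel) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  switch(kernel$type,
    linear = tcrossprod(X, Z),
    rbf = {
      s <- kernel$sigma
      if (is.null(s)) stop("rbf kernel requires sigma (set at fit time)")
      exp(-sq_dist(X, Z) / (2 * s^2))
    },
    polynomial = (tcrossprod(X, Z) + 1)^kernel$degree
  )
}

#' Gram matrix
#'
#' Pairwise kernel evaluations among the rows of `X`; symmetric and PSD,
#' with unit diagonal for the RBF kernel.
#'
#' @param X numeric matrix of samples.
#' @param kernel a [kernel_spec()].
#' @return N x N Gram matrix.
#' @export
gram_matrix <- function(X, kernel) {
  K <- kernel_cross(X, X, kernel)
  (K + t(K)) / 2
}

median_pairwise_distance <- function(X) {
  d <- sqrt(sq_dist(X, X))
  m <- stats::median(d[upper.tri(d)])
  if (!is.finite(m) || m <= 0) 1 else m
}

# N x C membership matrix with entries 1/C_i on class blocks (A_NC) and the
# per-class count vector, for labels y against sorted class order.
class_indicator <- function(y, classes) {
  C <- length(classes)
  N <- length(y)
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1L))
  A <- matrix(0, N, C)
  for (i in seq_len(C)) A[y == classes[i], i] <- 1 / counts[i]
  list(A = A, counts = counts)
}

#' Kernel-side between-class eigenbasis
#'
#' Assembles the C x C matrix `Phi_b^T Phi_b` from Gram blocks, where
#' `Phi_b` has columns `sqrt(C_i/N) (phibar_i - phibar)` (class means minus
#' the global mean in kernel feature space), and returns its top-M
#' eigenpairs. With a linear kernel this reproduces, through
#' [kda_project()], the direct-space whitened LDA projection.
#'
#' @param K N x N Gram matrix.
#' @param y labels aligned with the rows of `K`.
#' @param M number of components; there must be at least M eigenvalues above
#'   `1e-10`.
#' @return list with `E` (C x M eigenvectors), `lambda` (length-M positive
#'   eigenvalues, descending) and `classes`.
#' @export
kernel_between_class_basis <- function(K, y, M) {
  K <- as.matrix(K)
  N <- nrow(K)
  if (length(y) != N) stop("labels must match Gram matrix order")
  classes <- sort(unique(y))
  ind <- class_indicator(y, classes)
  A <- ind$A
  one <- matrix(1, N, 1L)
  AtKA <- crossprod(A, K %*% A)            # classmean' K classmean
  AtK1 <- crossprod(A, K %*% one)          # C x 1
  oneK1 <- drop(crossprod(one, K %*% one)) # scalar
  inner <- AtKA -
    (AtK1 %*% matrix(1, 1L, length(classes))) / N -
    (matrix(1, length(classes), 1L) %*% t(AtK1)) / N +
    oneK1 / N^2
  Bh <- sqrt(ind$counts)
  G <- (Bh * inner) * rep(Bh, each = length(classes)) / N # B^1/2 inner B^1/2 / N
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  pos <- sum(eg$values > 1e-10)
  if (pos < M) {
    stop(sprintf("only %d positive between-class eigenvalues; M = %d requested",
                 pos, M))
  }
  list(E = fix_signs(eg$vectors[, seq_len(M), drop = FALSE]),
       lambda = eg$values[seq_len(M)], classes = classes)
}

#' Fit a (kernel) discriminant feature extractor and Bayes classifier
#'
#' The training pipeline: build the Gram matrix, extract the M-dimensional
#' between-class eigenbasis (M defaults to `min(C-1, rank)`), project all
#' training samples, and estimate per-class means, `(alpha, gamma)`-
#' regularized covariances and priors for the Mahalanobis/Bayes rule.
#'
#' `alpha` shrinks each class covariance toward the pooled covariance;
#' `gamma` shrinks toward a scaled identity. `reg_preset = TRUE` selects the
#' fixed setting `alpha = 1`, `gamma = (tr(Sbar/N) + M)/M` (clamped to 1
#' with a warning when it exceeds 1, as it typically does).
#'
#' @param X training matrix, n x J.
#' @param y training labels (>= 2 classes).
#' @param kernel a [kernel_spec()]; default RBF with median-distance sigma.
#' @param alpha,gamma regularization parameters in `[0, 1]`.
#' @param M projected dimensionality; default `min(C-1, rank(S_b))`.
#' @param reg_preset use the fixed `(alpha, gamma)` preset described above.
#' @return An object of class `kda_model`.
#' @export
kda_fit <- function(X, y, kernel = kernel_spec("rbf"),
                    alpha = 0.5, gamma = 0.1, M = NULL, reg_preset = FALSE) {
  X <- as.matrix(X)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (kernel$type == "rbf" && is.null(kernel$sigma)) {
    kernel$sigma <- median_pairwise_distance(X)
  }
  classes <- sort(unique(y))
  C <- length(classes)
  if (C < 2L) stop("kda_fit requires at least 2 classes")
  K <- gram_matrix(X, kernel)
  if (is.null(M)) M <- C - 1L
  basis <- kernel_between_class_basis(K, y, M)
  M <- length(basis$lambda)
  model <- structure(
    list(kernel = kernel, Xtrain = X, y = y, classes = classes,
         counts = class_indicator(y, classes)$counts, N = nrow(X), M = M,
         E = basis$E, lambda = basis$lambda,
         alpha = alpha, gamma = gamma),
    class = "kda_model"
  )
  Ytr <- kda_project(X, model)
  if (reg_preset) {
    alpha <- 1
    Sbar <- pooled_within_scatter(Ytr, y, classes)
    gamma_raw <- (sum(diag(Sbar / model$N)) + M) / M
    gamma <- min(1, gamma_raw)
    if (gamma_raw > 1) {
      warning(sprintf("preset gamma = %.4g exceeds 1; clamped to 1", gamma_raw))
    }
    model$alpha <- alpha
    model$gamma <- gamma
  }
  model$class_means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(Ytr[y == cl, , drop = FALSE])
  }))
  model$sigmas <- regularized_covariance(Ytr, y, model$alpha, model$gamma)
  model$priors <- model$counts / model$N
  model$train_proj <- Ytr
  model
}

#' @export
print.kda_model <- function(x, ...) {
  cat(sprintf(
    "kda_model: %s kernel, C = %d classes, M = %d, alpha = %.3g, gamma = %.3g\n",
    x$kernel$type, length(x$classes), x$M, x$alpha, x$gamma
  ))
  invisible(x)
}

#' Project samples into the discriminant feature space
#'
#' Computes `ybar = Lambda^{-1} E^T Phi_b^T phi(z)` for each sample, where
#' `Phi_b^T phi(z)` is evaluated implicitly through kernel evaluations
#' against the stored training set. With a linear kernel this equals the
#' direct projection `X U` (up to per-axis sign).
#'
#' @param samples m x J matrix.
#' @param model a fitted [kda_fit()] model.
#' @return m x M matrix of projected features.
#' @export
kda_project <- function(samples, model) {
  stopifnot(inherits(model, "kda_model"))
  samples <- as.matrix(samples)
  if (ncol(samples) != ncol(model$Xtrain)) stop("feature dimension mismatch")
  kz <- kernel_cross(model$Xtrain, samples, model$kernel) # N x m
  ind <- class_indicator(model$y, model$classes)
  N <- model$N
  # Phi_b^T phi(z) = B^{1/2}/sqrt(N) * (A^T kz - 1_C (1_N^T kz)/N)
  Atk <- crossprod(ind$A, kz)                       # C x m
  colk <- matrix(colSums(kz) / N, length(model$classes), ncol(kz), byrow = TRUE)
  Pb <- sqrt(ind$counts) * (Atk - colk) / sqrt(N)   # C x m
  t(crossprod(model$E, Pb) / model$lambda)          # m x M
}

pooled_within_scatter <- function(Y, y, classes) {
  M <- ncol(Y)
  S <- matrix(0, M, M)
  for (cl in classes) {
    Yc <- sweep(Y[y == cl, , drop = FALSE], 2L,
                colMeans(Y[y == cl, , drop = FALSE]))
    S <- S + crossprod(Yc)
  }
  S
}

#' Regularized per-class covariances
#'
#' For each class i with unnormalized scatter `Si` about its own mean and
#' pooled scatter `S = sum_i Si`:
#' `Sigma_i(alpha) = ((1-alpha) Si + alpha S) / Ci(alpha)` with
#' `Ci(alpha) = (1-alpha) Ci + alpha N`, and
#' `Sigma_i(alpha, gamma) = (1-gamma) Sigma_i(alpha) +
#'  (gamma/M) tr(Sigma_i(alpha)) I`.
#' `alpha = 1` gives every class the pooled matrix `S/N`; `gamma = 1` gives
#' a scalar multiple of the identity. The result is positive definite for
#' any `gamma > 0`.
#'
#' @param Y projected features, n x M.
#' @param y labels.
#' @param alpha,gamma regularization parameters in `[0, 1]`.
#' @return named list of M x M symmetric matrices, one per sorted class.
#' @export
regularized_covariance <- function(Y, y, alpha, gamma) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  Y <- as.matrix(Y)
  M <- ncol(Y)
  classes <- sort(unique(y))
  N <- nrow(Y)
  Si <- lapply(classes, function(cl) {
    Yc <- sweep(Y[y == cl, , drop = FALSE], 2L,
                colMeans(Y[y == cl, , drop = FALSE]))
    crossprod(Yc)
  })
  S <- Reduce(`+`, Si)
  out <- lapply(seq_along(classes), function(i) {
    Ci <- sum(y == classes[i])
    Ca <- (1 - alpha) * Ci + alpha * N
    Sa <- ((1 - alpha) * Si[[i]] + alpha * S) / Ca
    Sg <- (1 - gamma) * Sa + (gamma / M) * sum(diag(Sa)) * diag(M)
    (Sg + t(Sg)) / 2
  })
  names(out) <- as.character(classes)
  out
}

#' Mahalanobis/Bayes classification in the discriminant space
#'
#' Scores each sample against every class with
#' `d_i(q) = (q - m_i)^T Sigma_i^{-1} (q - m_i) + ln|Sigma_i| - 2 ln pi_i`
#' and returns the argmin class (ties to the lowest class index). For binary
#' problems a real-valued score for the positive class is returned as
#' `d_neg - d_pos` for downstream ROC analysis.
#'
#' @param Q m x M matrix of projected samples (a vector is treated as one
#'   sample).
#' @param model a fitted [kda_fit()] model.
#' @return list with `class` (predicted labels), `d` (m x C score matrix)
#'   and, for two-class models, `score` (positive-class score per sample).
#' @export
mahalanobis_classify <- function(Q, model) {
  stopifnot(inherits(model, "kda_model"))
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L)
  Q <- as.matrix(Q)
  if (ncol(Q) != model$M) stop("samples must have M = ", model$M, " columns")
  C <- length(model$classes)
  d <- matrix(NA_real_, nrow(Q), C)
  for (i in seq_len(C)) {
    Sg <- model$sigmas[[i]]
    R <- tryCatch(chol(Sg), error = function(e) {
      stop(sprintf("covariance for class %s is singular", model$classes[i]))
    })
    logdet <- 2 * sum(log(diag(R)))
    diffs <- sweep(Q, 2L, model$class_means[i, ])
    z <- backsolve(R, t(diffs), transpose = TRUE)
    d[, i] <- colSums(z^2) + logdet - 2 * log(model$priors[i])
  }
  pred <- model$classes[max.col(-d, ties.method = "first")]
  out <- list(class = pred, d = d)
  if (C == 2L) out$score <- d[, 1L] - d[, 2L]
  out
}
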