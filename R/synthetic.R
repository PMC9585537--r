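#' Specification of a synthetic clinical table
#'
#' Describes the stochastic world the pipeline assumes: two classes of
#' class-conditional Gaussian records, a configurable fraction of rows
#' replaced by inflated-covariance "noise" draws (what the K-means filter is
#' meant to remove), and a configurable fraction of cells masked as missing.
#'
#' Defaults mirror the clinical setting the pipeline targets: 125 positive /
#' 157 negative records (44.33% / 55.67% prevalence), 13 mixed-scale
#' attributes, unit-variance features with a one-standard-deviation mean
#' shift between classes, 5% injected outliers and no missingness.
#'
#' @param n_per_class integer(2), rows per class (positive class first).
#' @param means list of two length-J mean vectors.
#' @param covariances list of two J x J symmetric positive-definite matrices.
#' @param outlier_fraction fraction of rows (in `[0,1)`) replaced by draws
#'   with 25x inflated covariance.
#' @param missing_fraction fraction of cells (in `[0,1)`) masked at random.
#' @param seed integer seed; identical seeds give byte-identical tables.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(125L, 157L),
                           means = list(rep(1, 13), rep(0, 13)),
                           covariances = list(diag(13), diag(13)),
                           outlier_fraction = 0.05,
                           missing_fraction = 0,
                           seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  stopifnot(
    length(n_per_class) == 2L, all(n_per_class >= 1L),
    length(means) == 2L, length(covariances) == 2L,
    outlier_fraction >= 0, outlier_fraction < 1,
    missing_fraction >= 0, missing_fraction < 1
  )
  J <- length(means[[1L]])
  if (length(means[[2L]]) != J) stop("class mean vectors must share a length")
  for (S in covariances) {
    S <- as.matrix(S)
    if (!identical(dim(S), c(J, J))) stop("covariance dimensions must match means")
    if (max(abs(S - t(S))) > 1e-8) stop("covariance must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("covariance must be positive definite")
    }
  }
  structure(
    list(n_per_class = n_per_class, means = means,
         covariances = lapply(covariances, as.matrix),
         outlier_fraction = outlier_fraction,
         missing_fraction = missing_fraction, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Draw n rows from N(mu, Sigma) via the Cholesky factor.
rmvn <- function(n, mu, Sigma) {
  J <- length(mu)
  Z <- matrix(stats::rnorm(n * J), n, J)
  sweep(Z %*% chol(Sigma), 2L, mu, "+")
}

#' Generate a synthetic feature table
#'
#' Rows are drawn class-conditionally from the two Gaussians of the spec
#' (labels 1 then 0, counts exactly `n_per_class`). An `outlier_fraction`
#' of rows, chosen uniformly at random, are then replaced by draws from the
#' same class mean with covariance inflated 25x and flagged in the table's
#' `outlier` provenance vector (labels are preserved). Finally a
#' `missing_fraction` of cells is masked uniformly at random.
#'
#' @param spec a [synthetic_spec].
#' @return A [feature_table] with provenance flags in `$outlier`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    n1 <- spec$n_per_class[1L]
    n0 <- spec$n_per_class[2L]
    n <- n1 + n0
    J <- length(spec$means[[1L]])
    X <- rbind(
      rmvn(n1, spec$means[[1L]], spec$covariances[[1L]]),
      rmvn(n0, spec$means[[2L]], spec$covariances[[2L]])
    )
    y <- c(rep(1L, n1), rep(0L, n0))
    outlier <- rep(FALSE, n)
    n_out <- floor(spec$outlier_fraction * n)
    if (n_out > 0L) {
      ridx <- sample(n, n_out)
      for (i in ridx) {
        cls <- if (y[i] == 1L) 1L else 2L
        X[i, ] <- rmvn(1L, spec$means[[cls]], 25 * spec$covariances[[cls]])
      }
      outlier[ridx] <- TRUE
    }
    missing <- matrix(FALSE, n, J)
    n_miss <- floor(spec$missing_fraction * n * J)
    if (n_miss > 0L) missing[sample(n * J, n_miss)] <- TRUE
    X[missing] <- 0
    nm <- if (J == 13L) uci_heart_names() else paste0("V", seq_len(J))
    feature_table(X, y, missing = missing, names = nm, outlier = outlier)
  })
}
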