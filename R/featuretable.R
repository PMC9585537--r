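#' Feature table container
#'
#' A `feature_table` holds a samples x attributes numeric matrix together with
#' per-sample integer labels, a missingness mask of the same shape as the
#' matrix, and attribute names. It is the common currency of the pipeline:
#' the UCI reader, the synthetic generator, the noise filter and the
#' discriminant/graph stages all consume and produce this class.
#'
#' @param X numeric matrix, n samples x J attributes.
#' @param y integer labels, length n (raw 0-4 codes or binarized 0/1).
#' @param missing logical matrix, same shape as `X`; `TRUE` marks a value that
#'   was absent in the source (rendered as `?` in the UCI dialect). Defaults
#'   to all-`FALSE`.
#' @param names character vector of attribute identifiers, length J. Defaults
#'   to `colnames(X)` or `V1..VJ`.
#' @param outlier optional logical vector, length n: provenance flags set by
#'   [generate_synthetic()] on rows replaced by inflated-covariance draws.
#'
#' @return An object of class `feature_table`: a list with elements `X`, `y`,
#'   `missing`, `names`, `outlier`.
#' @seealso [read_uci_heart()], [generate_synthetic()], [impute_missing()]
#' @export
feature_table <- function(X, y, missing = NULL, names = NULL, outlier = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  J <- ncol(X)
  if (n < 1L || J < 1L) stop("feature_table requires n >= 1 and J >= 1")
  y <- as.integer(y)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (is.null(missing)) {
    missing <- matrix(FALSE, n, J)
  } else {
    missing <- as.matrix(missing)
    if (!identical(dim(missing), dim(X))) stop("missing mask shape must equal X shape")
    storage.mode(missing) <- "logical"
  }
  if (is.null(names)) {
    names <- colnames(X)
    if (is.null(names)) names <- paste0("V", seq_len(J))
  }
  if (length(names) != J) stop("names must have length ncol(X)")
  colnames(X) <- names
  colnames(missing) <- names
  if (!is.null(outlier)) {
    outlier <- as.logical(outlier)
    if (length(outlier) != n) stop("outlier flags must have length nrow(X)")
  }
  structure(
    list(X = X, y = y, missing = missing, names = names, outlier = outlier),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d samples x %d attributes (%d missing cells)\n",
    nrow(x$X), ncol(x$X), sum(x$missing)
  ))
  cat("labels:", paste(utils::head(sort(unique(x$y)), 10L), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

# subset rows, preserving mask and provenance flags
ft_subset <- function(t, idx) {
  feature_table(
    t$X[idx, , drop = FALSE], t$y[idx],
    missing = t$missing[idx, , drop = FALSE],
    names = t$names,
    outlier = if (!is.null(t$outlier)) t$outlier[idx]
  )
}

# The 14-attribute convention used throughout the published UCI heart studies:
# 13 predictors + the 0-4 target. Categorical codes get mode imputation.
uci_heart_names <- function() {
  c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
    "thalach", "exang", "oldpeak", "slope", "ca", "thal")
}

uci_heart_categorical <- function() {
  c("sex", "cp", "fbs", "restecg", "exang", "slope", "ca", "thal")
}

# 1-based positions of the 14 standard attributes inside the 76-attribute raw
# record (documented attribute numbers: age=3 ... num=58).
uci_raw76_subset <- function() {
  c(age = 3L, sex = 4L, cp = 9L, trestbps = 10L, chol = 12L, fbs = 16L,
    restecg = 19L, thalach = 32L, exang = 38L, oldpeak = 40L, slope = 41L,
    ca = 44L, thal = 51L, num = 58L)
}

#' Read a UCI heart-disease table
#'
#' Parses the comma-separated, headerless "processed" dialect of the UCI
#' heart-disease repository (13 predictors + integer target 0-4 as the last
#' column, `?` marking missing values), or the 76-attribute raw dialect from
#' which only the standard 14-attribute subset is retained.
#'
#' No row is silently dropped: a row with the wrong field count is an error
#' that reports the offending row number.
#'
#' @param path path to the data file.
#' @param dialect `"processed_14"` (default) or `"raw_76"`.
#' @return A [feature_table] with J = 13 predictor columns; the target column
#'   is separated into `y` and `missing` is `TRUE` wherever `?` occurred.
#' @export
read_uci_heart <- function(path, dialect = c("processed_14", "raw_76")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  if (dialect == "processed_14") {
    fields <- strsplit(lines, ",", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != 14L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed row %d: expected 14 fields, got %d",
                   bad[1L], nf[bad[1L]]))
    }
    m <- matrix(trimws(unlist(fields)), ncol = 14L, byrow = TRUE)
  } else {
    # raw dialect: 76 whitespace/comma separated tokens per record, possibly
    # wrapped over several physical lines; reshape the token stream.
    toks <- unlist(strsplit(paste(lines, collapse = " "), "[,[:space:]]+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) %% 76L != 0L) {
      stop(sprintf("malformed raw_76 stream: %d tokens is not a multiple of 76",
                   length(toks)))
    }
    m <- matrix(toks, ncol = 76L, byrow = TRUE)[, uci_raw76_subset(), drop = FALSE]
  }
  miss <- m == "?"
  vals <- suppressWarnings(as.numeric(m))
  if (any(is.na(vals) & !miss)) {
    bad <- which(rowSums(matrix(is.na(vals), nrow(m)) & !miss) > 0L)[1L]
    stop(sprintf("malformed row %d: non-numeric field", bad))
  }
  vals[miss] <- NA_real_
  vals <- matrix(vals, nrow = nrow(m))
  J <- ncol(vals) - 1L
  ytgt <- vals[, J + 1L]
  if (any(miss[, J + 1L])) stop("missing target value in row ",
                                which(miss[, J + 1L])[1L])
  X <- vals[, seq_len(J), drop = FALSE]
  X[miss[, seq_len(J), drop = FALSE]] <- 0 # sentinel-free; mask carries truth
  feature_table(X, as.integer(ytgt),
                missing = miss[, seq_len(J), drop = FALSE],
                names = uci_heart_names())
}

#' Write a feature table in the processed UCI dialect
#'
#' Inverse of [read_uci_heart()] for the `processed_14` dialect: comma
#' separated, no header, masked cells rendered as `?`, target last.
#'
#' @param t a [feature_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_uci_heart <- function(t, path) {
  stopifnot(inherits(t, "feature_table"))
  # %.17g guarantees an exact double round trip through the text file
  chr <- matrix(sprintf("%.17g", t$X), nrow = nrow(t$X))
  chr[t$missing] <- "?"
  rows <- apply(cbind(chr, as.character(t$y)), 1L, paste, collapse = ",")
  writeLines(rows, path)
  invisible(path)
}

#' Binarize the 0-4 heart-disease target
#'
#' The UCI target is an integer 0-4: 0 codes absence of disease, 1-4 code
#' increasing severity of presence. The study convention collapses these to
#' 0 (absent) vs 1 (present).
#'
#' @param y_raw integer vector with values in 0..4.
#' @return integer vector of 0/1 labels.
#' @export
binarize_target <- function(y_raw) {
  y_raw <- as.integer(y_raw)
  if (any(is.na(y_raw)) || any(y_raw < 0L | y_raw > 4L)) {
    stop("target values must be integers in 0..4")
  }
  as.integer(y_raw != 0L)
}

#' Impute masked values
#'
#' Replaces masked entries by a per-column statistic computed over the
#' non-missing entries of that column. With the default schema-aware
#' strategy, the categorical code columns of the UCI schema (sex, cp, fbs,
#' restecg, exang, slope, ca, thal) use the mode (ties to the smallest
#' value) and all other columns the median; `"median"` forces the median
#' everywhere.
#'
#' @param t a [feature_table].
#' @param strategy `"mode_for_categorical"` (default) or `"median"`.
#' @return A [feature_table] with an all-`FALSE` mask.
#' @export
impute_missing <- function(t, strategy = c("mode_for_categorical", "median")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(t, "feature_table"))
  if (!any(t$missing)) return(t)
  X <- t$X
  cat_cols <- if (strategy == "mode_for_categorical") {
    t$names %in% uci_heart_categorical()
  } else rep(FALSE, ncol(X))
  for (j in seq_len(ncol(X))) {
    mj <- t$missing[, j]
    if (!any(mj)) next
    obs <- X[!mj, j]
    if (length(obs) == 0L) stop("column '", t$names[j], "' is fully missing")
    fill <- if (cat_cols[j]) {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)]) # which.max ties -> first = smallest
    } else {
      stats::median(obs)
    }
    X[mj, j] <- fill
  }
  feature_table(X, t$y, names = t$names, outlier = t$outlier)
}

#' Z-score standardization fit on a training split
#'
#' Returns centering/scaling parameters estimated on `X` only, so that test
#' rows can be transformed with the training statistics. Constant columns
#' get unit scale.
#'
#' @param X numeric matrix (training rows).
#' @return list with `center`, `scale` and a `transform(newX)` closure.
#' @export
fit_standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  list(
    center = center, scale = scale,
    transform = function(newX) {
      sweep(sweep(as.matrix(newX), 2L, center, "-"), 2L, scale, "/")
    }
  )
}

#' Stratified train/test split
#'
#' @param y label vector.
#' @param train_frac fraction of each class assigned to the training split.
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  idx <- with_local_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      n_tr <- max(1L, round(train_frac * length(ix)))
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  list(train = sort(idx), test = setdiff(seq_along(y), idx))
}

# Run expr under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
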