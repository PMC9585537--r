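resolve_activation <- function(act) {
  if (is.function(act)) return(list(f = act, df = NULL))
  switch(act,
    identity = list(f = function(x) x, df = function(x, fx) 1),
    tanh = list(f = tanh, df = function(x, fx) 1 - fx^2),
    relu = list(f = function(x) pmax(x, 0), df = function(x, fx) (x > 0) * 1),
    stop("unknown activation: ", act)
  )
}

#' Polynomial graph-convolution layer
#'
#' One spectral-polynomial layer: output channel j is
#' `sigma( sum_i sum_k theta[i,j,k] L^k H[,i] + b_j )`, i.e. every
#' input-channel signal is passed through a degree-K Laplacian polynomial
#' filter, mixed across channels, shifted by a bias and activated
#' elementwise. Computed by repeated sparse multiplication with `L` (no
#' eigendecomposition), so the layer is K-hop localized.
#'
#' @param H n x F_in input node-feature matrix.
#' @param g a [graph_from_weights()] graph.
#' @param params list with `theta` (F_in x F_out x (K+1) array), `b`
#'   (length F_out) and `activation` (`"tanh"`, `"relu"`, `"identity"` or a
#'   function).
#' @return n x F_out matrix.
#' @export
gcn_layer <- function(H, g, params) {
  stopifnot(inherits(g, "cardiodx_graph"))
  H <- as.matrix(H)
  th <- params$theta
  if (length(dim(th)) != 3L) stop("theta must be a 3-d array F_in x F_out x (K+1)")
  if (dim(th)[1L] != ncol(H)) stop("theta input channels must match ncol(H)")
  if (nrow(H) != g$n) stop("H must have one row per node")
  act <- resolve_activation(params$activation %||% "identity")
  Kp1 <- dim(th)[3L]
  Z <- matrix(0, nrow(H), dim(th)[2L])
  P <- H
  for (k in seq_len(Kp1)) {
    if (k > 1L) P <- g$L %*% P
    Z <- Z + P %*% theta_slice(th, k)
  }
  Z <- sweep(Z, 2L, params$b %||% rep(0, ncol(Z)), "+")
  act$f(Z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# k-th (1-based) F_in x F_out coefficient matrix of a theta array,
# robust to single-channel dimensions
theta_slice <- function(th, k) {
  m <- th[, , k, drop = FALSE]
  dim(m) <- dim(th)[1:2]
  m
}

#' Graph-transformer attention layer
#'
#' Multi-head attention over graph neighbourhoods with edge-feature
#' modulation. Per head k and edge (i, j):
#' `what_ij = (Q h_i * K h_j / sqrt(d_k)) * (E e_ij)` (elementwise, a
#' d_k-vector), scalar score `s_ij = sum(what_ij)`, attention
#' `w_ij = softmax_j(s_ij)` over the neighbours of i, node update
#' `h'_i = O_h concat_k( sum_j w_ij V h_j )` and edge update
#' `e'_ij = O_e concat_k(what_ij)`. A node without neighbours attends to
#' itself (logged self-loop fallback).
#'
#' @param H n x d node features.
#' @param E n x n x d_e edge-feature array (entries used on edges only);
#'   `NULL` uses the edge weight as a scalar feature.
#' @param g a graph.
#' @param params list with `heads` (list per head of `Q`, `K`, `V`
#'   (d_k x d) and `Ew` (d_k x d_e)), `O_h` (d x H d_k), `O_e` (d x H d_k).
#' @return list with `H` (n x d), `E` (n x n x d updated edge features) and
#'   `attn` (n x n x H attention weights; each node's row sums to 1 over
#'   its neighbours).
#' @export
attention_layer <- function(H, E, g, params) {
  stopifnot(inherits(g, "cardiodx_graph"))
  H <- as.matrix(H)
  n <- nrow(H)
  d <- ncol(H)
  if (n != g$n) stop("H must have one row per node")
  if (is.null(E)) E <- array(g$W, dim = c(n, n, 1L))
  d_e <- dim(E)[3L]
  heads <- params$heads
  nH <- length(heads)
  d_k <- nrow(heads[[1L]]$Q)
  if (nH * d_k != ncol(params$O_h)) stop("O_h columns must equal H * d_k")
  neigh <- lapply(seq_len(n), function(i) which(g$W[i, ] > 0))
  attn <- array(0, dim = c(n, n, nH))
  Hcat <- matrix(0, n, nH * d_k)
  Ecat <- array(0, dim = c(n, n, nH * d_k))
  for (k in seq_len(nH)) {
    hd <- heads[[k]]
    Qh <- H %*% t(hd$Q) # n x d_k
    Kh <- H %*% t(hd$K)
    Vh <- H %*% t(hd$V)
    cols <- (k - 1L) * d_k + seq_len(d_k)
    for (i in seq_len(n)) {
      js <- neigh[[i]]
      if (length(js) == 0L) {
        message("attention_layer: node ", i, " has no neighbours; using a self-loop")
        js <- i
      }
      # per-neighbour modulated score vectors (length(js) x d_k)
      Em <- matrix(E[i, js, ], length(js), d_e)
      Emod <- Em %*% t(hd$Ew)
      what <- sweep(Kh[js, , drop = FALSE], 2L, Qh[i, ], "*") / sqrt(d_k) * Emod
      s <- rowSums(what)
      w <- exp(s - max(s))
      w <- w / sum(w)
      attn[i, js, k] <- w
      Hcat[i, cols] <- colSums(w * Vh[js, , drop = FALSE])
      Ecat[i, js, cols] <- what
    }
  }
  Hout <- Hcat %*% t(params$O_h)
  Eout <- array(0, dim = c(n, n, nrow(params$O_e)))
  for (i in seq_len(n)) {
    Eout[i, , ] <- matrix(Ecat[i, , ], n, nH * d_k) %*% t(params$O_e)
  }
  list(H = Hout, E = Eout, attn = attn)
}

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

gcn_init_params <- function(F0, hidden, C, g_c, K, seed, l_scale = 1) {
  with_local_seed(seed, {
    dims <- c(F0, hidden)
    layers <- lapply(seq_along(hidden), function(l) {
      fin <- dims[l]; fout <- dims[l + 1L]
      # scale theta_k down by ||L||^k so L^k H theta_k starts O(1) and the
      # tanh units are not born saturated (combinatorial L is unbounded)
      th <- array(stats::rnorm(fin * fout * (K + 1L),
                               sd = 0.3 / sqrt(fin * (K + 1L))),
                  dim = c(fin, fout, K + 1L))
      for (k in 0:K) th[, , k + 1L] <- th[, , k + 1L] / l_scale^k
      list(theta = th, b = rep(0, fout))
    })
    hlast <- hidden[length(hidden)]
    list(
      layers = layers,
      Wc = matrix(stats::rnorm(hlast * C, sd = 0.3 / sqrt(hlast)), hlast, C),
      bc = rep(0, C),
      Wk = matrix(stats::rnorm(hlast * g_c, sd = 0.3 / sqrt(hlast)), hlast, g_c),
      bk = rep(0, g_c)
    )
  })
}

gcn_forward <- function(params, g, X, K) {
  cache <- list(H = list(as.matrix(X)))
  H <- as.matrix(X)
  Pk <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    th <- params$layers[[l]]$theta
    Z <- matrix(0, nrow(H), dim(th)[2L])
    P <- H
    Ps <- list(P)
    for (k in seq_len(K)) {
      P <- g$L %*% P
      Ps[[k + 1L]] <- P
    }
    for (k in 0:K) Z <- Z + Ps[[k + 1L]] %*% theta_slice(th, k + 1L)
    Z <- sweep(Z, 2L, params$layers[[l]]$b, "+")
    H <- tanh(Z)
    Pk[[l]] <- Ps
    cache$H[[l + 1L]] <- H
  }
  Sc <- sweep(H %*% params$Wc, 2L, params$bc, "+")
  Sk <- sweep(H %*% params$Wk, 2L, params$bk, "+")
  cache$P <- row_softmax(Sc)
  cache$Y <- row_softmax(Sk)
  cache$Pk <- Pk
  cache
}

# backprop from head-input gradients (dS: class head, dSk: cluster head)
# through the dense heads and the polynomial conv trunk
gcn_backward <- function(params, g, fw, dS, dSk, K) {
  Hlast <- fw$H[[length(fw$H)]]
  grads <- list(
    Wc = crossprod(Hlast, dS), bc = colSums(dS),
    Wk = crossprod(Hlast, dSk), bk = colSums(dSk)
  )
  dH <- dS %*% t(params$Wc) + dSk %*% t(params$Wk)
  grads$layers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    Hout <- fw$H[[l + 1L]]
    dZ <- dH * (1 - Hout^2)
    th <- params$layers[[l]]$theta
    dth <- array(0, dim = dim(th))
    for (k in 0:K) {
      dth[, , k + 1L] <- crossprod(fw$Pk[[l]][[k + 1L]], dZ)
    }
    db <- colSums(dZ)
    # dH_{l-1} = sum_k L^k dZ theta_k^T (L symmetric)
    Q <- dZ
    dHprev <- Q %*% t(theta_slice(th, 1L))
    for (k in seq_len(K)) {
      Q <- g$L %*% Q
      dHprev <- dHprev + Q %*% t(theta_slice(th, k + 1L))
    }
    grads$layers[[l]] <- list(theta = dth, b = db)
    dH <- dHprev
  }
  grads
}

grad_zip <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- grad_zip(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

grad_clip <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  gn <- sqrt(sum(rapply(grads, function(x) sum(x^2), how = "unlist")))
  if (gn > clip_norm) {
    grads <- rapply(grads, function(x) x * clip_norm / gn, how = "replace")
  }
  grads
}

# cross-entropy + lambda_cut * mincut loss with full analytic gradients,
# returned per loss term so the optimizer can clip them separately
gcn_loss_grads <- function(params, g, X, y_idx, train_mask, K, lambda_cut) {
  fw <- gcn_forward(params, g, X, K)
  n_tr <- sum(train_mask)
  P <- fw$P
  eps <- 1e-12
  ce <- -mean(log(P[cbind(which(train_mask), y_idx[train_mask])] + eps))
  cut <- mincut_loss(fw$Y, g, gradient = lambda_cut > 0)
  cut_val <- if (lambda_cut > 0) cut$value else as.numeric(cut)
  loss <- ce + lambda_cut * cut_val

  C <- ncol(P)
  dS <- matrix(0, g$n, C)
  tr_i <- which(train_mask)
  dS[tr_i, ] <- P[tr_i, , drop = FALSE]
  dS[cbind(tr_i, y_idx[tr_i])] <- dS[cbind(tr_i, y_idx[tr_i])] - 1
  dS <- dS / n_tr
  zeroSk <- matrix(0, g$n, ncol(fw$Y))
  grads_ce <- gcn_backward(params, g, fw, dS, zeroSk, K)

  grads_cut <- NULL
  if (lambda_cut > 0) {
    dY <- lambda_cut * cut$grad
    Y <- fw$Y
    dSk <- Y * (dY - rowSums(dY * Y)) # softmax backward, rowwise
    grads_cut <- gcn_backward(params, g, fw, 0 * dS, dSk, K)
  }
  grads <- if (is.null(grads_cut)) grads_ce else {
    grad_zip(grads_ce, grads_cut, `+`)
  }
  list(loss = loss, ce = ce, cut = cut_val, grads = grads,
       grads_ce = grads_ce, grads_cut = grads_cut, forward = fw)
}

#' Train the spectral graph convolutional classifier
#'
#' Transductive node classification: all samples (training and evaluation)
#' share one patient-similarity graph; only the nodes flagged in
#' `train_mask` contribute to the cross-entropy term. The network is a
#' stack of degree-K polynomial Laplacian convolution layers with tanh
#' activations and two dense softmax heads on the shared trunk: a class
#' head (cross-entropy) and a cluster head whose [mincut_loss()] acts as a
#' normalized-min-cut auxiliary regularizer. Optimized by full-batch
#' gradient descent with momentum using exact analytic gradients.
#'
#' @param g a [graph_from_weights()] graph over all n samples.
#' @param X n x F node-feature matrix.
#' @param y labels for all nodes (evaluation labels are never used in the
#'   loss; they may be `NA` outside `train_mask`).
#' @param train_mask logical length-n vector of labelled nodes.
#' @param hidden hidden channel widths, one per convolution layer.
#' @param K polynomial filter order.
#' @param g_c cluster count of the min-cut head.
#' @param lambda_cut weight of the min-cut term.
#' @param lr,momentum SGD-with-momentum hyperparameters. The step size
#'   decays as `lr / (1 + lr_decay * epoch / epochs)`.
#' @param lr_decay learning-rate decay factor (0 = constant step).
#' @param epochs training epochs.
#' @param checkpoints epochs at which node probabilities are snapshotted.
#' @param clip_norm global gradient-norm ceiling (the min-cut balance term
#'   has O(n^2)-scale gradients that would otherwise saturate the softmax
#'   heads in the first epochs); `Inf` disables clipping.
#' @param seed integer seed for parameter initialization.
#' @return object of class `gcn_model`: `params`, `classes`, `prob` (final
#'   n x C probabilities), `pred` (final labels), `log` (per-epoch losses),
#'   `checkpoints` (list of epoch/prob/pred snapshots) and the
#'   architecture settings.
#' @export
gcn_fit <- function(g, X, y, train_mask, hidden = c(8L, 8L), K = 2L,
                    g_c = 2L, lambda_cut = 0.1, lr = 0.02, momentum = 0.9,
                    lr_decay = 4, epochs = 500L,
                    checkpoints = c(100L, 200L, 300L, 400L, 500L),
                    clip_norm = 1, seed = 1L) {
  stopifnot(inherits(g, "cardiodx_graph"))
  X <- as.matrix(X)
  if (nrow(X) != g$n || length(y) != g$n || length(train_mask) != g$n) {
    stop("X, y and train_mask must all cover the n graph nodes")
  }
  if (!any(train_mask)) stop("train_mask selects no nodes")
  classes <- sort(unique(y[train_mask]))
  y_idx <- match(y, classes)
  l_scale <- max(1, norm(g$L, type = "2"))
  params <- gcn_init_params(ncol(X), hidden, length(classes), g_c, K, seed,
                            l_scale = l_scale)
  vel <- rapply(params, function(p) 0 * p, how = "replace")
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    ce = numeric(0), cut = numeric(0))
  snaps <- list()
  checkpoints <- sort(unique(pmin(checkpoints, epochs)))
  for (ep in seq_len(epochs)) {
    lg <- gcn_loss_grads(params, g, X, y_idx, train_mask, K, lambda_cut)
    # the two terms live on very different scales (CE is O(1), the min-cut
    # balance penalty O(n^2)); clip each term's gradient separately so
    # neither drowns the other, then sum
    lg$grads <- if (is.null(lg$grads_cut)) grad_clip(lg$grads_ce, clip_norm)
    else grad_zip(grad_clip(lg$grads_ce, clip_norm),
                  grad_clip(lg$grads_cut, clip_norm), `+`)
    # momentum update over the nested parameter list
    lr_ep <- lr / (1 + lr_decay * ep / epochs)
    upd <- function(p, v, gr) {
      v2 <- momentum * v - lr_ep * gr
      list(p = p + v2, v = v2)
    }
    for (nm in c("Wc", "bc", "Wk", "bk")) {
      u <- upd(params[[nm]], vel[[nm]], lg$grads[[nm]])
      params[[nm]] <- u$p; vel[[nm]] <- u$v
    }
    for (l in seq_along(params$layers)) {
      for (nm in c("theta", "b")) {
        u <- upd(params$layers[[l]][[nm]], vel$layers[[l]][[nm]],
                 lg$grads$layers[[l]][[nm]])
        params$layers[[l]][[nm]] <- u$p; vel$layers[[l]][[nm]] <- u$v
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = lg$loss,
                                 ce = lg$ce, cut = lg$cut))
    if (ep %in% checkpoints) {
      fw <- gcn_forward(params, g, X, K)
      snaps[[as.character(ep)]] <- list(
        epoch = ep, prob = fw$P,
        pred = classes[max.col(fw$P, ties.method = "first")]
      )
    }
  }
  fw <- gcn_forward(params, g, X, K)
  structure(
    list(params = params, classes = classes, prob = fw$P,
         pred = classes[max.col(fw$P, ties.method = "first")],
         cluster_assignment = fw$Y, log = log, checkpoints = snaps,
         hidden = hidden, K = K, g_c = g_c, lambda_cut = lambda_cut,
         seed = seed),
    class = "gcn_model"
  )
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf(
    "gcn_model: %d conv layers (hidden %s), K = %d, %d epochs, final loss %.4f\n",
    length(x$hidden), paste(x$hidden, collapse = "/"), x$K,
    max(x$log$epoch), x$log$loss[nrow(x$log)]
  ))
  invisible(x)
}
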