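# Minimal dense reverse-mode machinery for the four network architectures.
# Parameters are flat named lists of matrices/vectors; each architecture
# implements a forward returning (logits, cache) and a backward returning
# gradients for every parameter plus the input.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

addBias <- function(z, b) sweep(z, 2L, b, "+")

# ---- Adam ----------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, weight_decay = 5e-4,
                     skip = character(0)) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    if (nm %in% skip || is.null(grads[[nm]])) next
    g <- grads[[nm]] + weight_decay * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

# ---- losses --------------------------------------------------------------

# Cross-entropy of 2-class logits against 0/1 labels, restricted to `which`
# rows (transductive masking); returns loss and gradient wrt logits.
ceLoss <- function(logits, y01, which = NULL) {
  n_all <- nrow(logits)
  if (is.null(which)) which <- seq_len(n_all)
  p <- softmaxRows(logits[which, , drop = FALSE])
  yy <- y01[which]
  n <- length(which)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), yy + 1L)], 1e-300)))
  g <- matrix(0, n_all, 2L)
  gp <- p
  gp[cbind(seq_len(n), yy + 1L)] <- gp[cbind(seq_len(n), yy + 1L)] - 1
  g[which, ] <- gp / n
  list(loss = loss, grad = g)
}

# ---- Chebyshev graph convolution ----------------------------------------

#' Chebyshev graph convolution
#'
#' Computes `sum_{k=0}^{K-1} T_k(L~) X W_k` where `T_0 = I`, `T_1 = L~`,
#' `T_k = 2 L~ T_{k-1} - T_{k-2}` is the Chebyshev polynomial basis of the
#' rescaled Laplacian. With `K = 1` the graph is ignored and the layer is a
#' per-node linear map `X W_0`.
#'
#' @param X node features (n x f).
#' @param lt rescaled Laplacian from [scaledLaplacian()].
#' @param W list of K weight matrices (f x c).
#' @param b optional bias (length c).
#' @return n x c output features.
#' @export
chebGconv <- function(X, lt, W, b = NULL) {
  stopifnot2(length(W) >= 1L, "K must be >= 1")
  for (k in seq_along(W))
    if (nrow(W[[k]]) != ncol(X) || nrow(lt) != nrow(X))
      stop("dimension mismatch in Chebyshev convolution", call. = FALSE)
  out <- chebLayerForward(lt, X, W, b %||% numeric(ncol(W[[1L]])))
  out$Z
}

# Forward with cached polynomial products; R-form (propagate X W_k) keeps
# the recursion in output-channel space.
chebLayerForward <- function(lt, X, Ws, b) {
  K <- length(Ws)
  Pall <- vector("list", K)
  Z <- matrix(0, nrow(X), ncol(Ws[[1L]]))
  for (k in seq_len(K)) {
    R <- X %*% Ws[[k]]
    P <- vector("list", k)
    P[[1L]] <- R
    if (k >= 2L) P[[2L]] <- lt %*% R
    if (k >= 3L) for (m in 3L:k) P[[m]] <- 2 * (lt %*% P[[m - 1L]]) - P[[m - 2L]]
    Pall[[k]] <- P
    Z <- Z + P[[k]]
  }
  list(Z = addBias(Z, b), P = Pall)
}

# Backward; optionally accumulates the gradient with respect to the
# rescaled Laplacian (needed when the graph itself is trainable).
chebLayerBackward <- function(lt, X, Ws, cache, G, need_lt_grad = FALSE) {
  K <- length(Ws)
  gX <- matrix(0, nrow(X), ncol(X))
  gW <- vector("list", K)
  gLt <- if (need_lt_grad) matrix(0, nrow(lt), ncol(lt)) else NULL
  for (k in seq_len(K)) {
    P <- cache$P[[k]]
    pend <- vector("list", k)
    pend[[k]] <- G
    if (k >= 3L) for (m in k:3L) {
      gm <- pend[[m]]
      if (need_lt_grad) gLt <- gLt + 2 * tcrossprod(gm, P[[m - 1L]])
      pend[[m - 1L]] <- (pend[[m - 1L]] %||% 0) + 2 * (lt %*% gm)
      pend[[m - 2L]] <- (pend[[m - 2L]] %||% 0) - gm
    }
    if (k >= 2L) {
      gm <- pend[[2L]]
      if (need_lt_grad) gLt <- gLt + tcrossprod(gm, P[[1L]])
      pend[[1L]] <- (pend[[1L]] %||% 0) + lt %*% gm
    }
    gR <- pend[[1L]]
    gW[[k]] <- crossprod(X, gR)
    gX <- gX + tcrossprod(gR, Ws[[k]])
  }
  list(gX = gX, gW = gW, gb = colSums(G), gLt = gLt)
}
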