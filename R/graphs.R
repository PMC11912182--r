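#' Binary same-site population graph
#'
#' Subjects are connected with weight 1 iff they were imaged at the same
#' collection site, 0 otherwise; the diagonal is zero.
#'
#' @param sites character/factor vector of per-subject site labels.
#' @return n x n symmetric 0/1 matrix.
#' @export
buildSiteGraph <- function(sites) {
  stopifnot2(length(sites) > 0L, "sites must be non-empty")
  w <- outer(as.character(sites), as.character(sites), "==") * 1
  diag(w) <- 0
  w
}

#' Rescaled graph Laplacian for Chebyshev filters
#'
#' Computes `L~ = 2 L / lambda_max - I` where `L = I - D^{-1/2} W D^{-1/2}`
#' is the symmetric normalized Laplacian. Degree-zero (isolated) nodes are
#' given a unit self-connection in the normalized adjacency, so their rows
#' of `L` are zero and of `L~` are `-1` on the diagonal; an entirely empty
#' graph therefore yields `L~ = -I` (the Chebyshev basis then reduces to a
#' per-node map). `lambda_max` is computed by dense eigendecomposition up
#' to n = 2000 and by power iteration (tolerance 1e-6) beyond.
#'
#' @param w symmetric nonnegative weight matrix.
#' @return the rescaled Laplacian matrix, with attributes `lambda_max`.
#' @export
scaledLaplacian <- function(w) {
  stopifnot2(isSymmetricTol(w, 1e-8), "graph weights must be symmetric")
  if (any(w < 0)) stop("negative edge weights are not allowed", call. = FALSE)
  n <- nrow(w)
  d <- rowSums(w)
  dih <- ifelse(d > 0, 1 / sqrt(d), 0)
  ahat <- w * tcrossprod(dih)
  iso <- d <= 0
  if (any(iso)) diag(ahat)[iso] <- 1
  L <- diag(n) - ahat
  lmax <- if (n <= 2000L) {
    max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  } else {
    # power iteration on the shifted operator 2I - L (spectrum >= 0)
    v <- rep(1 / sqrt(n), n); prev <- 0
    for (it in seq_len(1000L)) {
      v2 <- 2 * v - L %*% v
      nv <- sqrt(sum(v2^2)); v <- drop(v2) / nv
      if (abs(nv - prev) < 1e-6) break
      prev <- nv
    }
    2 - prev
  }
  if (lmax < 1e-9) lmax <- 2
  lt <- 2 * L / lmax - diag(n)
  attr(lt, "lambda_max") <- lmax
  lt
}

#' Initialize pairwise association encoder parameters
#'
#' The PAE maps each subject's non-imaging encoding (sex one-hot plus site
#' one-hot) through a linear embedding `h = A p`, and scores a pair by a
#' logistic affine function of the pair-symmetric features
#' `[|h_i - h_j| , h_i * h_j]`, giving an edge weight in (0, 1).
#'
#' @param p_dim length of the per-subject phenotype encoding.
#' @param embed_dim embedding width.
#' @param seed initialization seed.
#' @return parameter list (`A`, `a_abs`, `a_prod`, `b`).
#' @export
paeInit <- function(p_dim, embed_dim = 8L, seed = 1L) {
  withSeed(seed, list(
    A = matrix(stats::rnorm(embed_dim * p_dim, 0, 0.3), embed_dim, p_dim),
    a_abs = stats::rnorm(embed_dim, 0, 0.3),
    a_prod = stats::rnorm(embed_dim, 0, 0.3),
    b = 0))
}

#' One-hot sex + site encoding consumed by the PAE
#' @param pheno phenotype table with `sex` and `site` columns.
#' @return subjects x (2 + n_sites) 0/1 matrix.
#' @export
paeEncoding <- function(pheno) {
  sites <- sort(unique(as.character(pheno$site)))
  enc <- cbind(sexM = as.numeric(pheno$sex == "M"),
               sexF = as.numeric(pheno$sex == "F"),
               do.call(cbind, lapply(sites, function(s)
                 as.numeric(pheno$site == s))))
  colnames(enc) <- c("sexM", "sexF", paste0("site_", sites))
  rownames(enc) <- pheno$id
  enc
}

#' Adaptive population-graph edge weights from the PAE
#'
#' Dense, pair-order-invariant edge weights in (0, 1), differentiable with
#' respect to the PAE parameters (see [paeGradient()]), forming the
#' trainable population graph of the edge-variational graph network.
#'
#' @param enc subjects x p encoding ([paeEncoding()]).
#' @param params PAE parameters ([paeInit()]).
#' @return n x n symmetric matrix of weights in (0, 1).
#' @export
paeEdgeWeights <- function(enc, params) {
  stopifnot2(!anyNA(enc), "phenotype encoding contains missing values")
  H <- enc %*% t(params$A)                     # n x e
  pre <- H %*% (params$a_prod * t(H)) + params$b
  for (k in seq_along(params$a_abs))
    pre <- pre + params$a_abs[k] * abs(outer(H[, k], H[, k], "-"))
  sigmoid(pre)
}

#' Gradient of a scalar loss through the PAE edge weights
#'
#' Given `dL/dW` for the emitted weight matrix, returns gradients for the
#' PAE parameters (backpropagation through the logistic pair score and the
#' linear embedding).
#'
#' @param enc,params as in [paeEdgeWeights()].
#' @param w the weights returned by [paeEdgeWeights()].
#' @param gw matrix of upstream gradients `dL/dW` (same shape as `w`).
#' @return list of gradients matching `params`.
#' @export
paeGradient <- function(enc, params, w, gw) {
  H <- enc %*% t(params$A)
  s <- gw * w * (1 - w)                        # dL/d pre-activation
  sy <- s + t(s)
  e <- length(params$a_abs)
  g_aabs <- numeric(e); g_aprod <- numeric(e)
  gH <- (sy %*% H) * rep(params$a_prod, each = nrow(H))
  for (k in seq_len(e)) {
    dk <- outer(H[, k], H[, k], "-")
    g_aabs[k] <- sum(s * abs(dk))
    g_aprod[k] <- drop(H[, k] %*% s %*% H[, k])
    gH[, k] <- gH[, k] + params$a_abs[k] * rowSums(sy * sign(dk))
  }
  list(A = t(gH) %*% enc, a_abs = g_aabs, a_prod = g_aprod, b = sum(s))
}

#' Random edge dropout on a population graph
#'
#' During training each undirected edge is independently zeroed with
#' probability `rate` and surviving weights are rescaled by `1/(1-rate)`;
#' at evaluation time the graph is returned unchanged. The diagonal is
#' never dropped.
#'
#' @param w symmetric weight matrix.
#' @param rate drop probability in `[0, 1)`.
#' @param seed optional seed for the mask.
#' @param training apply the mask (`TRUE`) or the identity (`FALSE`).
#' @return list with the dropped `w` and the applied `mask` multiplier
#'   matrix (all ones at evaluation).
#' @export
edgeDropout <- function(w, rate, seed = NULL, training = TRUE) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  n <- nrow(w)
  if (!training || rate == 0) return(list(w = w, mask = matrix(1, n, n)))
  keep <- withSeed(seed, stats::runif(n * (n - 1L) / 2) >= rate)
  mask <- matrixFromEdges(as.numeric(keep) / (1 - rate), n, diag = 1)
  list(w = w * mask, mask = mask)
}
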