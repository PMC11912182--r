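# Transductive graph architectures: all nodes and the full population
# graph are present at training time; the loss and checkpoint selection
# only ever see training/validation node labels.

checkMasks <- function(masks, n) {
  stopifnot2(all(c("train", "val", "test") %in% names(masks)),
             "masks must contain train/val/test")
  m <- vapply(masks[c("train", "val", "test")], function(x) {
    stopifnot2(is.logical(x) && length(x) == n, "masks must be logical of length n")
    x
  }, logical(n))
  if (any(rowSums(m) > 1L)) stop("mask overlap", call. = FALSE)
  masks
}

# ---- GCN -----------------------------------------------------------------

gcnInit <- function(N, hidden, K) {
  mk <- function(nin, nout) lapply(seq_len(K), function(k) glorot(nin, nout))
  list(G1 = mk(N, hidden[1L]), b1 = numeric(hidden[1L]),
       G2 = mk(hidden[1L], hidden[2L]), b2 = numeric(hidden[2L]),
       G3 = mk(hidden[2L], 2L), b3 = numeric(2L))
}

gcnForward <- function(params, X, lt, masks = NULL) {
  f1 <- chebLayerForward(lt, X, params$G1, params$b1)
  a1 <- relu(f1$Z); d1 <- applyMask(a1, masks$m1)
  f2 <- chebLayerForward(lt, d1, params$G2, params$b2)
  a2 <- relu(f2$Z); d2 <- applyMask(a2, masks$m2)
  f3 <- chebLayerForward(lt, d2, params$G3, params$b3)
  list(logits = f3$Z,
       cache = list(X = X, f1 = f1, a1 = a1, d1 = d1, f2 = f2, a2 = a2,
                    d2 = d2, f3 = f3, masks = masks))
}

gcnBackward <- function(params, cache, lt, G) {
  b3 <- chebLayerBackward(lt, cache$d2, params$G3, cache$f3, G)
  g <- applyMask(b3$gX, cache$masks$m2) * (cache$f2$Z > 0)
  b2 <- chebLayerBackward(lt, cache$d1, params$G2, cache$f2, g)
  g <- applyMask(b2$gX, cache$masks$m1) * (cache$f1$Z > 0)
  b1 <- chebLayerBackward(lt, cache$X, params$G1, cache$f1, g)
  list(grads = list(G1 = b1$gW, b1 = b1$gb, G2 = b2$gW, b2 = b2$gb,
                    G3 = b3$gW, b3 = b3$gb), gX = b1$gX)
}

# Adam treats the parameter list flatly; Chebyshev weight lists get
# list-valued entries, which adamStep handles element-wise via recursion.
flattenParams <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      for (k in seq_along(p[[nm]]))
        out[[paste0(nm, ".", k)]] <- p[[nm]][[k]]
    } else out[[nm]] <- p[[nm]]
  }
  out
}

unflattenParams <- function(flat, template) {
  for (nm in names(template)) {
    if (is.list(template[[nm]])) {
      for (k in seq_along(template[[nm]]))
        template[[nm]][[k]] <- flat[[paste0(nm, ".", k)]]
    } else template[[nm]] <- flat[[nm]]
  }
  template
}

graphAdamStep <- function(params, grads, opt, spec, skip = character(0)) {
  fp <- flattenParams(params); fg <- flattenParams(grads)
  st <- adamStep(fp, fg, opt, lr = spec$lr, weight_decay = spec$weight_decay,
                 skip = skip)
  list(params = unflattenParams(st$params, params), opt = st$state)
}

#' Train the Chebyshev graph convolutional network on the site graph
#'
#' Transductive training: every node's features and the full population
#' graph (same-site indicator by default) are visible, but the
#' cross-entropy loss is masked to training nodes and the iteration count
#' is selected on validation-node accuracy; test labels never touch the
#' loss or the selection. Three Chebyshev layers N-128-128-2 (order
#' `K = 3`) with dropout between layers.
#'
#' @param X_all standardized features for all nodes (n x N).
#' @param graph site label vector (turned into [buildSiteGraph()]) or a
#'   precomputed symmetric weight matrix.
#' @param y labels for all nodes (test labels are only carried, never used).
#' @param masks list of logical `train`, `val`, `test` masks (no overlap).
#' @param spec a [modelSpec()] for `"gcn"`.
#' @return a [TrainedClassifier-class] (`GraphClassifier`) with cached
#'   all-node scores.
#' @export
trainGCN <- function(X_all, graph, y, masks, spec = NULL) {
  X <- as.matrix(X_all)
  spec <- spec %||% modelSpec("gcn", ncol(X))
  masks <- checkMasks(masks, nrow(X))
  y01 <- labelTo01(y)
  w <- if (is.matrix(graph)) graph else buildSiteGraph(graph)
  lt <- scaledLaplacian(w)
  n <- nrow(X)
  tr <- which(masks$train); va <- which(masks$val)
  withSeed(spec$seed, {
    params <- gcnInit(spec$input_dim, spec$hidden, spec$K)
    opt0 <- adamInit(flattenParams(params))
    stepFn <- function(params, opt) {
      dm <- list(m1 = dropMask(n, spec$hidden[1L], spec$dropout),
                 m2 = dropMask(n, spec$hidden[2L], spec$dropout))
      fw <- gcnForward(params, X, lt, dm)
      ls <- ceLoss(fw$logits, y01, which = tr)
      bw <- gcnBackward(params, fw$cache, lt, ls$grad)
      st <- graphAdamStep(params, bw$grads, opt, spec)
      list(params = st$params, opt = st$opt, loss = ls$loss)
    }
    accFn <- function(params) {
      lg <- gcnForward(params, X, lt)$logits
      mean((lg[va, 2L] > lg[va, 1L]) == (y01[va] == 1L))
    }
    fit <- checkpointTrainGraph(params, opt0, stepFn, accFn, spec)
    scores <- softmaxRows(gcnForward(fit$params, X, lt)$logits)
    colnames(scores) <- c("td", "autism")
    methods::new("GraphClassifier", architecture = "gcn",
                 featureIds = colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
                 featureRange = featureRangeOf(X[masks$train, , drop = FALSE]),
                 seed = spec$seed, params = fit$params, spec = unclass(spec),
                 history = fit$history,
                 selectedIteration = as.integer(fit$iteration),
                 X = X, graph = list(lt = lt), masks = masks, scores = scores)
  })
}

# identical to checkpointTrain but with an externally initialized optimizer
checkpointTrainGraph <- function(params, opt, stepFn, accFn, spec) {
  hist <- data.frame(iteration = integer(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, params = params, iter = 0L)
  for (e in seq_len(spec$epochs_max)) {
    st <- stepFn(params, opt)
    params <- st$params; opt <- st$opt
    if (!is.finite(st$loss))
      stop("training loss became non-finite at epoch ", e, call. = FALSE)
    if (e %% spec$checkpoint_every == 0L) {
      acc <- accFn(params)
      hist <- rbind(hist, data.frame(iteration = e, val_accuracy = acc))
      if (acc > best$acc) best <- list(acc = acc, params = params, iter = e)
    }
  }
  list(params = best$params, iteration = best$iter, history = hist)
}

# ---- EV-GCN --------------------------------------------------------------

evgcnInit <- function(N, spec, enc_dim) {
  K <- spec$K; ch <- spec$gc_channels
  mk <- function(nin, nout) lapply(seq_len(K), function(k) glorot(nin, nout))
  p <- list()
  dims <- c(N, rep(ch, spec$n_gc))
  for (l in seq_len(spec$n_gc)) {
    p[[paste0("G", l)]] <- mk(dims[l], dims[l + 1L])
    p[[paste0("bg", l)]] <- numeric(dims[l + 1L])
  }
  fused <- ch * spec$n_gc
  p$Wm1 <- glorot(fused, spec$mlp_hidden); p$bm1 <- numeric(spec$mlp_hidden)
  p$Wm2 <- glorot(spec$mlp_hidden, 2L); p$bm2 <- numeric(2L)
  pae <- paeInit(enc_dim, spec$embed_dim, seed = NULL)
  # paeInit with seed = NULL draws from the ambient (already seeded) stream
  p$pae.A <- pae$A; p$pae.a_abs <- pae$a_abs
  p$pae.a_prod <- pae$a_prod; p$pae.b <- pae$b
  p
}

paeParamsOf <- function(params)
  list(A = params$pae.A, a_abs = params$pae.a_abs,
       a_prod = params$pae.a_prod, b = params$pae.b)

# The PAE consumes one-hot sex/site encodings, so subjects fall into at
# most 2 x n_sites distinct encoding groups; edge weights are computed on
# the unique rows and expanded through the group-membership matrix M
# (W = M W_u M'), which also pools the upstream gradient exactly
# (gW_u = M' gW M).
encGroups <- function(enc) {
  key <- apply(enc, 1L, paste, collapse = "\r")
  grp <- match(key, unique(key))
  u <- max(grp)
  M <- matrix(0, nrow(enc), u)
  M[cbind(seq_len(nrow(enc)), grp)] <- 1
  list(M = M, encU = enc[match(seq_len(u), grp), , drop = FALSE])
}

# Forward through PAE graph -> edge dropout -> symmetric normalization ->
# four Chebyshev layers -> fusion -> MLP. The rescaled Laplacian of the
# learned graph uses the fixed lambda_max = 2 convention, L~ = -A_hat,
# which keeps the whole graph differentiable.
evgcnForward <- function(params, X, enc, spec, training = FALSE) {
  pae <- paeParamsOf(params)
  gr <- encGroups(enc)
  WU <- paeEdgeWeights(gr$encU, pae)
  W <- gr$M %*% tcrossprod(WU, gr$M)
  diag(W) <- 1
  ed <- edgeDropout(W, if (training) spec$edge_dropout else 0,
                    training = training)
  Wd <- ed$w
  d <- rowSums(Wd)
  dih <- 1 / sqrt(d)
  ahat <- Wd * tcrossprod(dih)
  lt <- -ahat
  H <- X; layers <- list()
  for (l in seq_len(spec$n_gc)) {
    f <- chebLayerForward(lt, H, params[[paste0("G", l)]],
                          params[[paste0("bg", l)]])
    layers[[l]] <- list(f = f, input = H)
    H <- relu(f$Z)
    layers[[l]]$out <- H
  }
  fused <- do.call(cbind, lapply(layers, `[[`, "out"))
  m1 <- relu(addBias(fused %*% params$Wm1, params$bm1))
  logits <- addBias(m1 %*% params$Wm2, params$bm2)
  list(logits = logits,
       cache = list(X = X, W = W, WU = WU, groups = gr, mask = ed$mask,
                    Wd = Wd, d = d, dih = dih, lt = lt, layers = layers,
                    fused = fused, m1 = m1, enc = enc))
}

evgcnBackward <- function(params, cache, spec, G, need_graph_grad = TRUE) {
  gWm2 <- crossprod(cache$m1, G); gbm2 <- colSums(G)
  g <- tcrossprod(G, params$Wm2) * (cache$m1 > 0)
  gWm1 <- crossprod(cache$fused, g); gbm1 <- colSums(g)
  gFused <- tcrossprod(g, params$Wm1)
  ch <- spec$gc_channels
  grads <- list(Wm1 = gWm1, bm1 = gbm1, Wm2 = gWm2, bm2 = gbm2)
  gOut <- vector("list", spec$n_gc)
  for (l in seq_len(spec$n_gc))
    gOut[[l]] <- gFused[, ((l - 1L) * ch + 1L):(l * ch), drop = FALSE]
  gLt <- if (need_graph_grad) matrix(0, nrow(cache$lt), ncol(cache$lt)) else NULL
  gH <- NULL
  for (l in spec$n_gc:1L) {
    gout <- gOut[[l]]
    if (!is.null(gH)) gout <- gout + gH
    g <- gout * (cache$layers[[l]]$f$Z > 0)
    bl <- chebLayerBackward(cache$lt, cache$layers[[l]]$input,
                            params[[paste0("G", l)]], cache$layers[[l]]$f,
                            g, need_lt_grad = need_graph_grad)
    grads[[paste0("G", l)]] <- bl$gW
    grads[[paste0("bg", l)]] <- bl$gb
    if (need_graph_grad) gLt <- gLt + bl$gLt
    gH <- bl$gX
  }
  gX <- gH
  if (need_graph_grad) {
    gAhat <- -gLt
    dih <- cache$dih
    gWd <- gAhat * tcrossprod(dih)
    B <- (gAhat + t(gAhat)) * cache$Wd
    dd <- -0.5 * cache$d^(-1.5) * drop(B %*% dih)
    gWd <- gWd + matrix(dd, nrow(gWd), ncol(gWd))
    gW <- gWd * cache$mask
    diag(gW) <- 0   # diagonal is clamped to 1, not produced by the PAE
    gWU <- crossprod(cache$groups$M, gW %*% cache$groups$M)
    pg <- paeGradient(cache$groups$encU, paeParamsOf(params), cache$WU, gWU)
    grads$pae.A <- pg$A; grads$pae.a_abs <- pg$a_abs
    grads$pae.a_prod <- pg$a_prod; grads$pae.b <- pg$b
  }
  list(grads = grads, gX = gX)
}

#' Train the edge-variational graph network with a trainable PAE graph
#'
#' The pairwise association encoder builds a dense adaptive population
#' graph from sex and site one-hot encodings; edge dropout regularizes it
#' during training and the PAE parameters are updated by backpropagation
#' through the graph normalization. Four 16-channel Chebyshev layers are
#' fused into a 64-dim concatenation feeding a 64-256-2 MLP.
#'
#' @param X_all standardized features for all nodes.
#' @param pheno phenotype table (for [paeEncoding()]) or a precomputed
#'   encoding matrix.
#' @param y,masks,spec as in [trainGCN()] (spec architecture `"ev_gcn"`).
#' @return a `GraphClassifier`.
#' @export
trainEVGCN <- function(X_all, pheno, y, masks, spec = NULL) {
  X <- as.matrix(X_all)
  spec <- spec %||% modelSpec("ev_gcn", ncol(X))
  masks <- checkMasks(masks, nrow(X))
  y01 <- labelTo01(y)
  enc <- if (is.matrix(pheno)) pheno else paeEncoding(pheno)
  tr <- which(masks$train); va <- which(masks$val)
  skip <- if (isTRUE(spec$pae_trainable)) character(0)
          else c("pae.A", "pae.a_abs", "pae.a_prod", "pae.b")
  withSeed(spec$seed, {
    params <- evgcnInit(spec$input_dim, spec, ncol(enc))
    opt0 <- adamInit(flattenParams(params))
    stepFn <- function(params, opt) {
      fw <- evgcnForward(params, X, enc, spec, training = TRUE)
      ls <- ceLoss(fw$logits, y01, which = tr)
      bw <- evgcnBackward(params, fw$cache, spec, ls$grad,
                          need_graph_grad = isTRUE(spec$pae_trainable))
      st <- graphAdamStep(params, bw$grads, opt, spec, skip = skip)
      list(params = st$params, opt = st$opt, loss = ls$loss)
    }
    accFn <- function(params) {
      lg <- evgcnForward(params, X, enc, spec)$logits
      mean((lg[va, 2L] > lg[va, 1L]) == (y01[va] == 1L))
    }
    fit <- checkpointTrainGraph(params, opt0, stepFn, accFn, spec)
    scores <- softmaxRows(evgcnForward(fit$params, X, enc, spec)$logits)
    colnames(scores) <- c("td", "autism")
    methods::new("GraphClassifier", architecture = "ev_gcn",
                 featureIds = colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
                 featureRange = featureRangeOf(X[masks$train, , drop = FALSE]),
                 seed = spec$seed, params = fit$params, spec = unclass(spec),
                 history = fit$history,
                 selectedIteration = as.integer(fit$iteration),
                 X = X, graph = list(enc = enc), masks = masks,
                 scores = scores)
  })
}

# Pre-softmax autism logit of one node with its feature row replaced;
# shared by the gradient tests and SmoothGrad plumbing.
scoreLogitAt <- function(object, node, xnode = NULL, class = "autism") {
  X <- object@X
  if (!is.null(xnode)) X[node, ] <- xnode
  lg <- if (object@architecture == "gcn")
    gcnForward(object@params, X, object@graph$lt)$logits
  else evgcnForward(object@params, X, object@graph$enc, object@spec)$logits
  lg[node, if (class == "autism") 2L else 1L]
}

# ---- methods -------------------------------------------------------------

#' @rdname classScores
#' @export
setMethod("classScores", "GraphClassifier", function(object, newdata = NULL, ...) {
  idx <- newdata %||% seq_len(nrow(object@scores))
  object@scores[idx, , drop = FALSE]
})

#' @rdname inputGradient
#' @param xnode optional replacement feature row for the node.
#' @export
setMethod("inputGradient", "GraphClassifier", function(object, x,
                                                       class = "autism",
                                                       xnode = NULL, ...) {
  node <- as.integer(x)
  stopifnot2(length(node) == 1L && node >= 1L && node <= nrow(object@X),
             "x must be a single node index")
  cl <- match.arg(class, c("autism", "td"))
  X <- object@X
  if (!is.null(xnode)) X[node, ] <- xnode
  G <- matrix(0, nrow(X), 2L)
  G[node, if (cl == "autism") 2L else 1L] <- 1
  if (object@architecture == "gcn") {
    lt <- object@graph$lt
    fw <- gcnForward(object@params, X, lt)
    gX <- gcnBackward(object@params, fw$cache, lt, G)$gX
  } else {
    fw <- evgcnForward(object@params, X, object@graph$enc, object@spec)
    gX <- evgcnBackward(object@params, fw$cache, object@spec, G,
                        need_graph_grad = FALSE)$gX
  }
  gX[node, ]
})
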