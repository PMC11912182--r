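#' Model specification for the five classifier architectures
#'
#' Bundles architecture hyperparameters with the training budget. Layer
#' widths default to the reference configuration of each architecture:
#' FCN N-500-30-2 with dropout 0.5 after both hidden layers; AE-FCN with
#' encoder N-300-150, decoder 150-300-N and a classifier head N-300-16-2
#' consuming the reconstruction; GCN with three Chebyshev layers
#' N-128-128-2 on the site graph; EV-GCN with four 16-channel Chebyshev
#' layers whose outputs are fused into a 64-wide concatenation followed by
#' a 64-256-2 MLP. Optimization uses full-batch Adam (learning rate 1e-3,
#' 5e-3 for the graph models; weight decay 5e-4); the number of training
#' iterations is tuned on the validation set over a checkpoint grid.
#'
#' @param architecture one of `"svm"`, `"fcn"`, `"ae_fcn"`, `"gcn"`,
#'   `"ev_gcn"`.
#' @param input_dim number of input features N.
#' @param ... overrides of the architecture defaults listed above, e.g.
#'   `hidden`, `dropout`, `K`, `lr`, `epochs_max`, `checkpoint_every`,
#'   `C_grid` (svm), `head` (`"reconstruction"` or `"bottleneck"`, ae_fcn),
#'   `edge_dropout`/`pae_trainable`/`embed_dim` (ev_gcn), `seed`.
#' @return a `ModelSpec` list.
#' @export
modelSpec <- function(architecture, input_dim, ...) {
  archs <- c("svm", "fcn", "ae_fcn", "gcn", "ev_gcn")
  stopifnot2(architecture %in% archs,
             paste("architecture must be one of:", paste(archs, collapse = ", ")))
  base <- list(architecture = architecture, input_dim = as.integer(input_dim),
               weight_decay = 5e-4, epochs_max = 300L, checkpoint_every = 10L,
               seed = 1L)
  defaults <- switch(architecture,
    svm = list(C_grid = c(0.1, 1, 10)),
    fcn = list(hidden = c(500L, 30L), dropout = 0.5, lr = 1e-3),
    ae_fcn = list(enc_hidden = 300L, bottleneck = 150L,
                  clf_hidden = c(300L, 16L), head = "reconstruction",
                  mse_weight = 1, ce_weight = 1, lr = 1e-3),
    gcn = list(hidden = c(128L, 128L), K = 3L, dropout = 0.3, lr = 5e-3),
    ev_gcn = list(gc_channels = 16L, n_gc = 4L, mlp_hidden = 256L, K = 3L,
                  embed_dim = 8L, edge_dropout = 0.3, pae_trainable = TRUE,
                  lr = 5e-3))
  spec <- utils::modifyList(c(base, defaults), list(...))
  widths <- unlist(spec[names(spec) %in%
                          c("hidden", "enc_hidden", "bottleneck", "clf_hidden",
                            "gc_channels", "mlp_hidden")])
  stopifnot2(all(widths > 0), "layer widths must be positive")
  structure(spec, class = "ModelSpec")
}

dropMask <- function(n, p, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(n * p) >= rate) / (1 - rate), n, p)
}

applyMask <- function(a, mask) if (is.null(mask)) a else a * mask

# Shared training loop: full-batch steps with validation-selected
# checkpoint. `stepFn(params, opt)` performs one epoch and returns
# list(params, opt, loss); `accFn(params)` is validation accuracy.
checkpointTrain <- function(params, stepFn, accFn, spec) {
  opt <- adamInit(params)
  hist <- data.frame(iteration = integer(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, params = params, iter = 0L)
  for (e in seq_len(spec$epochs_max)) {
    st <- stepFn(params, opt)
    params <- st$params; opt <- st$opt
    if (!is.finite(st$loss))
      stop("training loss became non-finite at epoch ", e,
           " (architecture ", spec$architecture, ", lr ", spec$lr, ")",
           call. = FALSE)
    if (e %% spec$checkpoint_every == 0L) {
      acc <- accFn(params)
      hist <- rbind(hist, data.frame(iteration = e, val_accuracy = acc))
      if (acc > best$acc) best <- list(acc = acc, params = params, iter = e)
    }
  }
  list(params = best$params, iteration = best$iter, history = hist)
}

featureRangeOf <- function(X) {
  r <- apply(X, 2L, range)
  rownames(r) <- c("min", "max")
  r
}

# ---- FCN -----------------------------------------------------------------

fcnInit <- function(N, hidden) {
  list(W1 = glorot(N, hidden[1L]), b1 = numeric(hidden[1L]),
       W2 = glorot(hidden[1L], hidden[2L]), b2 = numeric(hidden[2L]),
       W3 = glorot(hidden[2L], 2L), b3 = numeric(2L))
}

fcnForward <- function(params, X, masks = NULL) {
  a1 <- relu(addBias(X %*% params$W1, params$b1))
  d1 <- applyMask(a1, masks$m1)
  a2 <- relu(addBias(d1 %*% params$W2, params$b2))
  d2 <- applyMask(a2, masks$m2)
  logits <- addBias(d2 %*% params$W3, params$b3)
  list(logits = logits,
       cache = list(X = X, a1 = a1, d1 = d1, a2 = a2, d2 = d2, masks = masks))
}

fcnBackward <- function(params, cache, G) {
  gW3 <- crossprod(cache$d2, G); gb3 <- colSums(G)
  g <- tcrossprod(G, params$W3)
  g <- applyMask(g, cache$masks$m2)
  g <- g * (cache$a2 > 0)
  gW2 <- crossprod(cache$d1, g); gb2 <- colSums(g)
  g <- tcrossprod(g, params$W2)
  g <- applyMask(g, cache$masks$m1)
  g <- g * (cache$a1 > 0)
  gW1 <- crossprod(cache$X, g); gb1 <- colSums(g)
  gX <- tcrossprod(g, params$W1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3), gX = gX)
}

#' Train the fully connected network classifier
#'
#' Three linear layers (N-500-30-2 by default) with dropout 0.5 after the
#' first and second layers, trained with full-batch Adam on the
#' cross-entropy loss; the iteration count is selected by validation
#' accuracy over the checkpoint grid. Deterministic given `spec$seed`.
#'
#' @param X,y standardized training features and binary labels.
#' @param X_val,y_val validation split used only to pick the iteration
#'   count.
#' @param spec a [modelSpec()] for `"fcn"`.
#' @return a [TrainedClassifier-class] (`NetClassifier`).
#' @export
trainFCN <- function(X, y, X_val, y_val, spec = NULL) {
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  spec <- spec %||% modelSpec("fcn", ncol(X))
  y01 <- labelTo01(y); yv <- labelTo01(y_val)
  n <- nrow(X)
  withSeed(spec$seed, {
    params <- fcnInit(spec$input_dim, spec$hidden)
    stepFn <- function(params, opt) {
      masks <- list(m1 = dropMask(n, spec$hidden[1L], spec$dropout),
                    m2 = dropMask(n, spec$hidden[2L], spec$dropout))
      fw <- fcnForward(params, X, masks)
      ls <- ceLoss(fw$logits, y01)
      bw <- fcnBackward(params, fw$cache, ls$grad)
      st <- adamStep(params, bw$grads, opt, lr = spec$lr,
                     weight_decay = spec$weight_decay)
      list(params = st$params, opt = st$state, loss = ls$loss)
    }
    accFn <- function(params)
      mean((fcnForward(params, X_val)$logits[, 2L] >
              fcnForward(params, X_val)$logits[, 1L]) == (yv == 1L))
    fit <- checkpointTrain(params, stepFn, accFn, spec)
    methods::new("NetClassifier", architecture = "fcn",
                 featureIds = colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
                 featureRange = featureRangeOf(X), seed = spec$seed,
                 params = fit$params, spec = unclass(spec),
                 history = fit$history,
                 selectedIteration = as.integer(fit$iteration))
  })
}

# ---- AE-FCN --------------------------------------------------------------

aefcnInit <- function(N, spec) {
  eh <- spec$enc_hidden; bt <- spec$bottleneck; ch <- spec$clf_hidden
  cin <- if (spec$head == "bottleneck") bt else N
  list(W1 = glorot(N, eh), b1 = numeric(eh),
       W2 = glorot(eh, bt), b2 = numeric(bt),
       W3 = glorot(bt, eh), b3 = numeric(eh),
       W4 = glorot(eh, N), b4 = numeric(N),
       W5 = glorot(cin, ch[1L]), b5 = numeric(ch[1L]),
       W6 = glorot(ch[1L], ch[2L]), b6 = numeric(ch[2L]),
       W7 = glorot(ch[2L], 2L), b7 = numeric(2L))
}

aefcnForward <- function(params, X, head = "reconstruction") {
  h1 <- relu(addBias(X %*% params$W1, params$b1))
  code <- relu(addBias(h1 %*% params$W2, params$b2))
  h3 <- relu(addBias(code %*% params$W3, params$b3))
  recon <- addBias(h3 %*% params$W4, params$b4)
  cin <- if (head == "bottleneck") code else recon
  h4 <- relu(addBias(cin %*% params$W5, params$b5))
  h5 <- relu(addBias(h4 %*% params$W6, params$b6))
  logits <- addBias(h5 %*% params$W7, params$b7)
  list(logits = logits, recon = recon,
       cache = list(X = X, h1 = h1, code = code, h3 = h3, recon = recon,
                    cin = cin, h4 = h4, h5 = h5, head = head))
}

# G: gradient wrt logits; gReconExtra: gradient wrt recon from the MSE term
aefcnBackward <- function(params, cache, G, gReconExtra = NULL) {
  gW7 <- crossprod(cache$h5, G); gb7 <- colSums(G)
  g <- tcrossprod(G, params$W7) * (cache$h5 > 0)
  gW6 <- crossprod(cache$h4, g); gb6 <- colSums(g)
  g <- tcrossprod(g, params$W6) * (cache$h4 > 0)
  gW5 <- crossprod(cache$cin, g); gb5 <- colSums(g)
  gCin <- tcrossprod(g, params$W5)
  if (cache$head == "bottleneck") {
    gRecon <- gReconExtra %||% matrix(0, nrow(cache$X), ncol(cache$X))
    gCode_extra <- gCin
  } else {
    gRecon <- gCin + (gReconExtra %||% 0)
    gCode_extra <- 0
  }
  gW4 <- crossprod(cache$h3, gRecon); gb4 <- colSums(gRecon)
  g <- tcrossprod(gRecon, params$W4) * (cache$h3 > 0)
  gW3 <- crossprod(cache$code, g); gb3 <- colSums(g)
  g <- (tcrossprod(g, params$W3) + gCode_extra) * (cache$code > 0)
  gW2 <- crossprod(cache$h1, g); gb2 <- colSums(g)
  g <- tcrossprod(g, params$W2) * (cache$h1 > 0)
  gW1 <- crossprod(cache$X, g); gb1 <- colSums(g)
  gX <- tcrossprod(g, params$W1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3,
                    b3 = gb3, W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5,
                    W6 = gW6, b6 = gb6, W7 = gW7, b7 = gb7), gX = gX)
}

#' Joint loss of the autoencoder-classifier at given parameters
#'
#' Total loss = mean squared reconstruction error plus cross-entropy of the
#' classifier head (unit weights by default; the weights are the
#' `mse_weight`/`ce_weight` spec fields).
#' @param params,X,y01 network parameters, inputs, 0/1 labels.
#' @param spec a [modelSpec()] for `"ae_fcn"`.
#' @return list with `total`, `mse`, `ce`.
#' @export
aefcnLoss <- function(params, X, y01, spec) {
  fw <- aefcnForward(params, X, spec$head)
  mse <- mean((fw$recon - X)^2)
  ce <- ceLoss(fw$logits, y01)$loss
  list(total = spec$mse_weight * mse + spec$ce_weight * ce, mse = mse, ce = ce)
}

#' Train the autoencoder-classifier
#'
#' Encoder N-300-150, decoder 150-300-N, and a classifier head that
#' consumes the reconstruction (N-300-16-2); trained end-to-end on the sum
#' of reconstruction MSE and classification cross-entropy. A
#' `head = "bottleneck"` spec variant feeds the 150-dim code to the
#' classifier instead.
#'
#' @inheritParams trainFCN
#' @param spec a [modelSpec()] for `"ae_fcn"`.
#' @return a `NetClassifier`.
#' @export
trainAEFCN <- function(X, y, X_val, y_val, spec = NULL) {
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  spec <- spec %||% modelSpec("ae_fcn", ncol(X))
  y01 <- labelTo01(y); yv <- labelTo01(y_val)
  n <- nrow(X); N <- ncol(X)
  withSeed(spec$seed, {
    params <- aefcnInit(spec$input_dim, spec)
    stepFn <- function(params, opt) {
      fw <- aefcnForward(params, X, spec$head)
      ls <- ceLoss(fw$logits, y01)
      mse <- mean((fw$recon - X)^2)
      gRecon <- spec$mse_weight * 2 * (fw$recon - X) / (n * N)
      bw <- aefcnBackward(params, fw$cache, spec$ce_weight * ls$grad, gRecon)
      st <- adamStep(params, bw$grads, opt, lr = spec$lr,
                     weight_decay = spec$weight_decay)
      list(params = st$params, opt = st$state,
           loss = spec$mse_weight * mse + spec$ce_weight * ls$loss)
    }
    accFn <- function(params) {
      lg <- aefcnForward(params, X_val, spec$head)$logits
      mean((lg[, 2L] > lg[, 1L]) == (yv == 1L))
    }
    fit <- checkpointTrain(params, stepFn, accFn, spec)
    methods::new("NetClassifier", architecture = "ae_fcn",
                 featureIds = colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
                 featureRange = featureRangeOf(X), seed = spec$seed,
                 params = fit$params, spec = unclass(spec),
                 history = fit$history,
                 selectedIteration = as.integer(fit$iteration))
  })
}

# ---- shared scoring / gradient methods ----------------------------------

netLogits <- function(object, X) {
  switch(object@architecture,
    fcn = fcnForward(object@params, X)$logits,
    ae_fcn = aefcnForward(object@params, X, object@spec$head)$logits,
    stop("unsupported architecture"))
}

#' @rdname classScores
#' @export
setMethod("classScores", "NetClassifier", function(object, newdata = NULL, ...) {
  X <- as.matrix(newdata)
  p <- softmaxRows(netLogits(object, X))
  colnames(p) <- c("td", "autism")
  p
})

#' @rdname inputGradient
#' @export
setMethod("inputGradient", "NetClassifier", function(object, x,
                                                     class = "autism", ...) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  cl <- match.arg(class, c("autism", "td"))
  G <- matrix(0, nrow(X), 2L)
  G[, if (cl == "autism") 2L else 1L] <- 1
  gX <- switch(object@architecture,
    fcn = {
      fw <- fcnForward(object@params, X)
      fcnBackward(object@params, fw$cache, G)$gX
    },
    ae_fcn = {
      fw <- aefcnForward(object@params, X, object@spec$head)
      aefcnBackward(object@params, fw$cache, G)$gX
    },
    stop("unsupported architecture"))
  if (nrow(gX) == 1L) drop(gX) else gX
})
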