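test_that("Chebyshev convolution matches the dense polynomial oracle", {
  set.seed(10)
  for (K in 1:4) {
    n <- 6L; f <- 5L; cch <- 3L
    w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
    lt <- scaledLaplacian(w)
    X <- matrix(rnorm(n * f), n, f)
    W <- lapply(seq_len(K), function(k) matrix(rnorm(f * cch), f, cch))
    expect_equal(chebGconv(X, lt, W), chebDenseOracle(X, lt, W),
                 tolerance = 1e-10)
  }
  # K = 1 ignores the graph entirely
  n <- 4L; X <- matrix(rnorm(8), 4, 2)
  W0 <- matrix(rnorm(4), 2, 2)
  lt <- scaledLaplacian(buildSiteGraph(c("A", "A", "B", "B")))
  expect_equal(chebGconv(X, lt, list(W0)), X %*% W0)
  # zero graph, K = 2: closed form X W0 - X W1
  ltz <- scaledLaplacian(matrix(0, 4, 4))
  W1 <- matrix(rnorm(4), 2, 2)
  expect_equal(chebGconv(X, ltz, list(W0, W1)), X %*% W0 - X %*% W1,
               tolerance = 1e-12)
  expect_error(chebGconv(X, lt, list(matrix(0, 3, 2))), "dimension")
})

test_that("class scores are probability rows for every architecture", {
  d <- separableData(n = 120L, p = 10L, seed = 31)
  sp <- list(epochs_max = 30L, checkpoint_every = 10L)
  svm <- trainSVM(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val])
  fcn <- trainFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val],
                  do.call(modelSpec, c(list("fcn", 10L, hidden = c(16L, 8L)), sp)))
  ae <- trainAEFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val],
                   do.call(modelSpec, c(list("ae_fcn", 10L, enc_hidden = 12L,
                                             bottleneck = 6L,
                                             clf_hidden = c(12L, 6L)), sp)))
  n <- nrow(d$X)
  sites <- rep(c("A", "B", "C"), length.out = n)
  masks <- list(train = seq_len(n) %in% d$train, val = seq_len(n) %in% d$val,
                test = seq_len(n) %in% d$test)
  gcn <- trainGCN(d$X, sites, d$y, masks,
                  do.call(modelSpec, c(list("gcn", 10L, hidden = c(8L, 8L)), sp)))
  ph <- S4Vectors::DataFrame(id = sprintf("p%d", seq_len(n)), site = sites,
                             sex = rep(c("M", "F"), length.out = n))
  ev <- trainEVGCN(d$X, ph, d$y, masks,
                   do.call(modelSpec, c(list("ev_gcn", 10L, gc_channels = 4L,
                                             mlp_hidden = 16L), sp)))
  for (m in list(svm, fcn, ae)) {
    sc <- classScores(m, d$X[d$test, ])
    expect_true(all(is.finite(sc)) && all(sc >= 0))
    expect_equal(unname(rowSums(sc)), rep(1, length(d$test)), tolerance = 1e-6)
  }
  for (m in list(gcn, ev)) {
    sc <- classScores(m, d$test)
    expect_true(all(is.finite(sc)) && all(sc >= 0))
    expect_equal(unname(rowSums(sc)), rep(1, length(d$test)), tolerance = 1e-6)
  }
})

test_that("input gradients match central finite differences", {
  d <- separableData(n = 80L, p = 8L, seed = 32)
  sp <- list(epochs_max = 20L, checkpoint_every = 10L)
  fcn <- trainFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val],
                  do.call(modelSpec, c(list("fcn", 8L, hidden = c(12L, 6L)), sp)))
  ae <- trainAEFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val],
                   do.call(modelSpec, c(list("ae_fcn", 8L, enc_hidden = 10L,
                                             bottleneck = 5L,
                                             clf_hidden = c(10L, 5L)), sp)))
  h <- 1e-4
  fdCheck <- function(fun, grad, x) {
    num <- vapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (fun(xp) - fun(xm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(grad - num)) / max(abs(num), 1e-8), 1e-3)
  }
  set.seed(1); x <- rnorm(8)
  fdCheck(function(z) connectomeBench:::netLogits(fcn, rbind(z))[, 2],
          inputGradient(fcn, x), x)
  fdCheck(function(z) connectomeBench:::netLogits(ae, rbind(z))[, 2],
          inputGradient(ae, x, class = "autism"), x)
  fdCheck(function(z) connectomeBench:::netLogits(ae, rbind(z))[, 1],
          inputGradient(ae, x, class = "td"), x)

  n <- nrow(d$X)
  sites <- rep(c("A", "B"), length.out = n)
  masks <- list(train = seq_len(n) %in% d$train, val = seq_len(n) %in% d$val,
                test = seq_len(n) %in% d$test)
  gcn <- trainGCN(d$X, sites, d$y, masks,
                  do.call(modelSpec, c(list("gcn", 8L, hidden = c(6L, 6L)), sp)))
  ph <- S4Vectors::DataFrame(id = sprintf("p%d", seq_len(n)), site = sites,
                             sex = rep(c("M", "F"), length.out = n))
  ev <- trainEVGCN(d$X, ph, d$y, masks,
                   do.call(modelSpec, c(list("ev_gcn", 8L, gc_channels = 4L,
                                             mlp_hidden = 12L), sp)))
  node <- d$test[1]
  for (m in list(gcn, ev)) {
    g <- inputGradient(m, node)
    x0 <- m@X[node, ]
    num <- vapply(seq_along(x0), function(i) {
      xp <- x0; xm <- x0
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      fp <- connectomeBench:::scoreLogitAt(m, node, xp)
      fm <- connectomeBench:::scoreLogitAt(m, node, xm)
      (fp - fm) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - num)) / max(abs(num), 1e-8), 1e-3)
  }
})

test_that("training is deterministic given spec, seed and data", {
  d <- separableData(n = 100L, p = 8L, seed = 33)
  sp <- modelSpec("fcn", 8L, hidden = c(12L, 6L), epochs_max = 30L, seed = 17L)
  m1 <- trainFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val], sp)
  m2 <- trainFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val], sp)
  expect_identical(m1@params, m2@params)
  expect_identical(classScores(m1, d$X[d$test, ]),
                   classScores(m2, d$X[d$test, ]))
  # two evaluation passes are bit-identical (dropout disabled at eval)
  expect_identical(classScores(m1, d$X[d$test, ]),
                   classScores(m1, d$X[d$test, ]))
})
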