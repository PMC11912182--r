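test_that("FCN separates planted-signal data and is at chance on permuted labels", {
  d <- separableData(n = 600L, p = 20L, n_signal = 5L, d = 2, seed = 41)
  sp <- modelSpec("fcn", 20L, epochs_max = 100L, seed = 2L)
  m <- trainFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val], sp)
  sc <- classScores(m, d$X[d$test, ])
  pred <- ifelse(sc[, "autism"] > 0.5, "autism", "td")
  expect_gte(classificationAccuracy(pred, d$y[d$test]), 0.95)

  set.seed(42)
  yperm <- sample(d$y)
  m0 <- trainFCN(d$X[d$train, ], yperm[d$train], d$X[d$val, ], yperm[d$val], sp)
  sc0 <- classScores(m0, d$X[d$test, ])
  pred0 <- ifelse(sc0[, "autism"] > 0.5, "autism", "td")
  expect_lt(abs(classificationAccuracy(pred0, yperm[d$test]) - 0.5), 0.08)
})

test_that("AE-FCN reconstruction loss descends and total loss matches a hand-summed oracle", {
  set.seed(43)
  N <- 8L; n <- 50L
  X <- matrix(rnorm(n * N), n, N)
  y <- rep(c("autism", "td"), 25)
  y01 <- as.integer(y == "autism")
  spec <- modelSpec("ae_fcn", N, enc_hidden = 6L, bottleneck = 3L,
                    clf_hidden = c(6L, 4L), seed = 4L)
  params <- connectomeBench:::withSeed(4L, connectomeBench:::aefcnInit(N, spec))

  # independent forward-pass oracle at initialization
  rl <- function(z) pmax(z, 0)
  h1 <- rl(sweep(X %*% params$W1, 2, params$b1, "+"))
  code <- rl(sweep(h1 %*% params$W2, 2, params$b2, "+"))
  h3 <- rl(sweep(code %*% params$W3, 2, params$b3, "+"))
  recon <- sweep(h3 %*% params$W4, 2, params$b4, "+")
  h4 <- rl(sweep(recon %*% params$W5, 2, params$b5, "+"))
  h5 <- rl(sweep(h4 %*% params$W6, 2, params$b6, "+"))
  logits <- sweep(h5 %*% params$W7, 2, params$b7, "+")
  pr <- exp(logits - apply(logits, 1, max))
  pr <- pr / rowSums(pr)
  oracle <- mean((recon - X)^2) -
    mean(log(pr[cbind(1:n, y01 + 1)]))
  got <- aefcnLoss(params, X, y01, spec)
  expect_equal(got$total, oracle, tolerance = 1e-12)

  # CE weight ablated: reconstruction MSE strictly decreases over the
  # first 10 full-batch gradient-descent epochs
  spec0 <- modelSpec("ae_fcn", N, enc_hidden = 6L, bottleneck = 3L,
                     clf_hidden = c(6L, 4L), ce_weight = 0, seed = 4L)
  p <- params
  mses <- numeric(11)
  mses[1] <- aefcnLoss(p, X, y01, spec0)$mse
  for (e in 1:10) {
    fw <- connectomeBench:::aefcnForward(p, X, spec0$head)
    gRecon <- 2 * (fw$recon - X) / (n * N)
    bw <- connectomeBench:::aefcnBackward(p, fw$cache,
                                          matrix(0, n, 2), gRecon)
    for (nm in names(p)) p[[nm]] <- p[[nm]] - 0.05 * bw$grads[[nm]]
    mses[e + 1] <- aefcnLoss(p, X, y01, spec0)$mse
  }
  expect_true(all(diff(mses) < 0))
})

test_that("AE-FCN learns separable data", {
  d <- separableData(n = 400L, p = 16L, n_signal = 5L, d = 2, seed = 44)
  sp <- modelSpec("ae_fcn", 16L, enc_hidden = 24L, bottleneck = 12L,
                  clf_hidden = c(24L, 8L), epochs_max = 80L, seed = 5L)
  m <- trainAEFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val], sp)
  sc <- classScores(m, d$X[d$test, ])
  pred <- ifelse(sc[, "autism"] > 0.5, "autism", "td")
  expect_gte(classificationAccuracy(pred, d$y[d$test]), 0.9)
})

test_that("GCN on a zero graph is a per-node map and its loss is masked", {
  d <- separableData(n = 60L, p = 6L, seed = 45)
  n <- nrow(d$X)
  masks <- list(train = seq_len(n) %in% d$train, val = seq_len(n) %in% d$val,
                test = seq_len(n) %in% d$test)
  sp <- modelSpec("gcn", 6L, hidden = c(6L, 6L), epochs_max = 20L, seed = 6L)
  sites <- sprintf("S%d", seq_len(n))  # all distinct -> empty graph
  m <- trainGCN(d$X, sites, d$y, masks, sp)
  node <- d$test[1]
  base <- connectomeBench:::scoreLogitAt(m, node)
  X2 <- m@X
  others <- setdiff(seq_len(n), node)
  X2[others, ] <- X2[others, ] + 5   # perturb every other node
  m2 <- m; m2@X <- X2
  expect_equal(connectomeBench:::scoreLogitAt(m2, node), base,
               tolerance = 1e-10)

  # leakage guard: flipping test labels leaves the trained weights
  # bit-identical
  yflip <- d$y
  yflip[d$test] <- ifelse(d$y[d$test] == "autism", "td", "autism")
  sites2 <- rep(c("A", "B", "C"), length.out = n)
  ma <- trainGCN(d$X, sites2, d$y, masks, sp)
  mb <- trainGCN(d$X, sites2, yflip, masks, sp)
  expect_identical(ma@params, mb@params)
  expect_error(trainGCN(d$X, sites2, d$y,
                        list(train = masks$train, val = masks$train,
                             test = masks$test), sp),
               "overlap")
})

test_that("GCN propagates site-aligned labels through the site graph", {
  set.seed(46)
  n_sites <- 8L; per <- 10L; n <- n_sites * per
  sites <- rep(sprintf("S%d", 1:n_sites), each = per)
  y <- ifelse(rep(1:n_sites, each = per) %% 2 == 0, "autism", "td")
  X <- matrix(rnorm(n * 10), n, 10)   # features carry no label signal
  idx <- unlist(lapply(split(seq_len(n), sites), function(s) s[1:6]))
  vidx <- unlist(lapply(split(seq_len(n), sites), function(s) s[7:8]))
  tidx <- setdiff(seq_len(n), c(idx, vidx))
  masks <- list(train = seq_len(n) %in% idx, val = seq_len(n) %in% vidx,
                test = seq_len(n) %in% tidx)
  sp <- modelSpec("gcn", 10L, hidden = c(16L, 16L), epochs_max = 150L,
                  seed = 7L)
  m <- trainGCN(X, sites, y, masks, sp)
  sc <- classScores(m, tidx)
  pred <- ifelse(sc[, "autism"] > 0.5, "autism", "td")
  expect_gte(classificationAccuracy(pred, y[tidx]), 0.9)
})

test_that("EV-GCN fuses four 16-channel layers into a 64-wide MLP input", {
  d <- separableData(n = 60L, p = 6L, seed = 47)
  n <- nrow(d$X)
  masks <- list(train = seq_len(n) %in% d$train, val = seq_len(n) %in% d$val,
                test = seq_len(n) %in% d$test)
  ph <- S4Vectors::DataFrame(id = sprintf("p%d", seq_len(n)),
                             site = rep(c("A", "B", "C"), length.out = n),
                             sex = rep(c("M", "F"), length.out = n))
  sp <- modelSpec("ev_gcn", 6L, epochs_max = 20L, seed = 8L)
  m <- trainEVGCN(d$X, ph, d$y, masks, sp)
  expect_equal(nrow(m@params$Wm1), 64L)  # 16 channels x 4 layers
  expect_equal(length(m@params$G4), 3L)  # Chebyshev order K = 3
  # evaluation is deterministic (edge dropout off)
  expect_identical(classScores(m, d$test), classScores(m, d$test))

  # trainable PAE performs at least comparably to a frozen PAE
  spF <- modelSpec("ev_gcn", 6L, epochs_max = 20L, seed = 8L,
                   pae_trainable = FALSE)
  mf <- trainEVGCN(d$X, ph, d$y, masks, spF)
  accOf <- function(mm) {
    sc <- classScores(mm, which(masks$val))
    classificationAccuracy(ifelse(sc[, "autism"] > 0.5, "autism", "td"),
                           d$y[masks$val])
  }
  expect_gte(accOf(m), accOf(mf) - 0.05)
  expect_false(identical(m@params$pae.A, mf@params$pae.A))
})

test_that("RBF SVM beats a linear kernel on XOR-patterned data", {
  set.seed(48)
  n <- 600L
  X <- matrix(runif(n * 2, -1, 1), n, 2)
  y <- ifelse(X[, 1] * X[, 2] > 0, "autism", "td")
  tr <- 1:300; va <- 301:400; te <- 401:600
  std <- fitStandardizer(X[tr, ])
  Xs <- applyStandardizer(std, X)
  m <- trainSVM(Xs[tr, ], y[tr], Xs[va, ], y[va])
  sc <- classScores(m, Xs[te, ])
  rbf_acc <- classificationAccuracy(
    ifelse(sc[, "autism"] > 0.5, "autism", "td"), y[te])
  expect_gt(rbf_acc, 0.9)
  lin <- e1071::svm(x = Xs[tr, ], y = factor(y[tr]), kernel = "linear",
                    scale = FALSE)
  lin_acc <- mean(as.character(predict(lin, Xs[te, ])) == y[te])
  expect_lte(lin_acc, 0.6)

  # linearly separable blobs: perfect training accuracy, and duplicating
  # every training point leaves the decision function unchanged
  d <- separableData(n = 200L, p = 4L, n_signal = 4L, d = 6, seed = 49)
  spc <- modelSpec("svm", 4L, C_grid = 10)  # hard-margin regime
  ms <- trainSVM(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val], spc)
  sct <- classScores(ms, d$X[d$train, ])
  expect_equal(classificationAccuracy(
    ifelse(sct[, "autism"] > 0.5, "autism", "td"), d$y[d$train]), 1)
  dup <- rbind(d$X[d$train, ], d$X[d$train, ])
  md <- trainSVM(dup, c(d$y[d$train], d$y[d$train]),
                 d$X[d$val, ], d$y[d$val], spc)
  dv1 <- connectomeBench:::decisionValues(ms@fit, d$X[d$test, ])
  dv2 <- connectomeBench:::decisionValues(md@fit, d$X[d$test, ])
  expect_lt(max(abs(dv1 - dv2)), 1e-2)
  expect_identical(sign(dv1), sign(dv2))
  expect_error(trainSVM(d$X[d$train, ], rep("td", length(d$train)),
                        d$X[d$val, ], d$y[d$val]), "single class")
})
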