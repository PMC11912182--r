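test_that("SmoothGrad of a linear scorer is exactly the absolute weights", {
  set.seed(81)
  w <- rnorm(7)
  m <- linearFCN(w)
  x <- rnorm(7)
  for (ns in c(0, 0.1, 0.5)) {
    sal <- smoothGrad(m, x, smoothGradConfig(noise_scale = ns, seed = 3))
    expect_equal(unname(sal), abs(w), tolerance = 1e-12)
  }
})

test_that("zero noise reduces SmoothGrad to the plain gradient; svm is rejected", {
  d <- separableData(n = 100L, p = 6L, seed = 82)
  m <- trainFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val],
                modelSpec("fcn", 6L, hidden = c(8L, 4L), epochs_max = 20L))
  x <- d$X[d$test[1], ]
  sal <- smoothGrad(m, x, smoothGradConfig(noise_scale = 0, seed = 1))
  expect_equal(unname(sal), unname(abs(inputGradient(m, x))),
               tolerance = 1e-12)
  # seed-determinism
  cfg <- smoothGradConfig(seed = 9)
  expect_identical(smoothGrad(m, x, cfg), smoothGrad(m, x, cfg))

  svm <- trainSVM(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val])
  expect_error(smoothGrad(svm, x), "svm")
})

test_that("averaged gradients match finite differences at the same noise points", {
  d <- separableData(n = 100L, p = 5L, seed = 83)
  m <- trainFCN(d$X[d$train, ], d$y[d$train], d$X[d$val, ], d$y[d$val],
                modelSpec("fcn", 5L, hidden = c(6L, 3L), epochs_max = 20L))
  x <- d$X[d$test[2], ]
  cfg <- smoothGradConfig(n_noisy = 4L, noise_scale = 0.1, seed = 13)
  sal <- smoothGrad(m, x, cfg)
  # replicate the seeded noise stream and average finite-difference
  # gradients of the autism logit at the same points
  rng <- m@featureRange["max", ] - m@featureRange["min", ]
  sdv <- cfg$noise_scale * rng
  h <- 1e-4
  fd <- connectomeBench:::withSeed(cfg$seed, {
    acc <- numeric(5)
    for (t in 1:4) {
      eps <- rnorm(5, 0, sdv)
      xe <- x + eps
      acc <- acc + vapply(1:5, function(i) {
        xp <- xe; xm <- xe
        xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
        (connectomeBench:::netLogits(m, rbind(xp))[, 2] -
           connectomeBench:::netLogits(m, rbind(xm))[, 2]) / (2 * h)
      }, numeric(1))
    }
    acc / 4
  })
  expect_lt(max(abs(unname(sal) - abs(fd))) / max(abs(fd)), 1e-3)
})

test_that("participant SNR matches the hand-computed example and is scale invariant", {
  stack <- cbind(f1 = 1:5, f2 = 2 * (1:5))
  r <- participantSNR(stack)
  expect_equal(r$per_feature$snr, rep(3 / sd(1:5), 2), tolerance = 1e-6)
  expect_equal(r$average, 1.897367, tolerance = 1e-6)
  expect_equal(r$n_flagged, 0L)

  r7 <- participantSNR(stack * 7)
  expect_equal(r7$average, r$average, tolerance = 1e-12)

  same <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  rs <- participantSNR(same)
  expect_equal(rs$n_flagged, 3L)
  expect_true(all(rs$per_feature$flagged))
  expect_true(is.nan(rs$average))
  expect_error(participantSNR(stack[1, , drop = FALSE]), "at least 2")
})

test_that("stability reports average SNR over repeats", {
  m <- cbind(repeat_1 = c(1, 4), repeat_2 = c(2, 5), repeat_3 = c(3, 6))
  rownames(m) <- c("a", "b")
  rep1 <- stabilityHistogram(m[, 1, drop = FALSE])
  expect_equal(unname(rep1@snr$snr), c(1, 4))
  r <- stabilityHistogram(m)
  expect_equal(unname(r@snr$snr), c(2, 5))
  expect_equal(sum(r@histogram$counts), 2L)
  m[1, 2] <- NA
  expect_error(stabilityHistogram(m), "missing repeat")
})

test_that("nodal strength sums incident edge saliency and conserves mass", {
  ei1 <- data.frame(i = 1L, j = 2L)
  s <- nodalStrength(5, ei1, n_regions = 4)
  expect_equal(s, c(5, 5, 0, 0))

  ei <- data.frame(i = c(1L, 1L, 3L), j = c(2L, 4L, 4L))
  sal <- c(1, 2, 4)
  expect_equal(nodalStrength(sal, ei, 4), c(3, 1, 4, 6))

  set.seed(84)
  ei6 <- edgeIndex(6)
  rsal <- runif(nrow(ei6))
  expect_equal(sum(nodalStrength(rsal, ei6)), 2 * sum(rsal))
  expect_error(nodalStrength(c(1), data.frame(i = 1L, j = 9L), 4), "unknown")

  expect_equal(zscoreMap(rep(2, 5)), rep(0, 5))
  z <- zscoreMap(c(1, 2, 3, 10))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("top features rank descending with id tie-breaks", {
  s <- c(b = 3, a = 5, c = 3, d = 1)
  expect_equal(topFeatures(s, 1)$feature_id, "a")
  t3 <- topFeatures(s, 3)
  expect_equal(t3$feature_id, c("a", "b", "c"))   # tie b/c broken by id
  expect_setequal(topFeatures(s, 4)$feature_id, names(s))
  expect_error(topFeatures(s, 5), "exceeds")
})

test_that("TP/TN/FP/FN groups partition the cohort and detect planted effects", {
  set.seed(85)
  n <- 240L
  labels <- rep(c("autism", "td"), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("planted", "null1", "null2")))
  X[, "planted"] <- X[, "planted"] + ifelse(labels == "autism", 1, -1)  # d=2
  preds <- labels
  flip <- sample(n, 30)
  preds[flip] <- ifelse(labels[flip] == "autism", "td", "autism")
  g <- groupBoxplotData(preds, labels, X)
  expect_equal(sum(g$sizes), n)
  expect_true(g$tested)
  expect_lt(g$tp_vs_tn[["planted"]], 0.01)
  expect_gt(g$tp_vs_tn[["null1"]], 0.01)

  gp <- groupBoxplotData(labels, labels, X)  # perfect classifier
  expect_equal(as.vector(gp$sizes[c("FP", "FN")]), c(0L, 0L))
  expect_true(all(is.na(gp$summary$q1[gp$summary$group %in% c("FP", "FN")])))

  # TP group empty: test flagged off
  g0 <- groupBoxplotData(rep("td", n), labels, X)
  expect_false(g0$tested)
  expect_true(all(is.na(g0$tp_vs_tn)))
})
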