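test_that("Pearson FC matches the direct covariance/SD formula", {
  set.seed(21)
  ts <- matrix(rnorm(3 * 50), 3, 50)
  fc <- pearsonFC(ts)
  for (i in 1:2) for (j in (i + 1):3) {
    x <- ts[i, ]; y <- ts[j, ]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(fc[i, j], oracle, tolerance = 1e-12)
  }
  expect_equal(diag(fc), rep(1, 3))

  ts2 <- rbind(a = 1:10, b = 1:10, c = 10:1) + 0
  fc2 <- pearsonFC(ts2)
  expect_equal(fc2[1, 2], 1)
  expect_equal(fc2[1, 3], -1)

  bad <- rbind(a = 1:10, roiX = rep(2, 10)) + 0
  expect_error(pearsonFC(bad), "roiX")
})

test_that("upper-triangle vectorization uses fixed row-major order and round-trips", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  diag(m) <- 1
  v <- vectorizeUpper(m)
  expect_equal(unname(v$values), c(0.1, 0.2, 0.3))
  expect_equal(v$edges$id, c("e1_2", "e1_3", "e2_3"))

  expect_equal(length(vectorizeUpper(diag(2) * 0 + 1)$values), 1L)
  expect_equal(unname(vectorizeUpper(diag(3))$values), c(0, 0, 0))
  expect_equal(nrow(edgeIndex(200)), 19900L)

  asym <- m; asym[1, 2] <- 0.5
  expect_error(vectorizeUpper(asym), "asymmetric")

  set.seed(2)
  r <- matrix(rnorm(64), 8, 8); r <- (r + t(r)) / 2; diag(r) <- 1
  v2 <- vectorizeUpper(r)
  expect_identical(matrixFromEdges(v2$values, 8), r)
})

test_that("structural assembly is label-ordered and complete", {
  set.seed(3)
  cort <- matrix(rnorm(68 * 9), 68, 9,
                 dimnames = list(sprintf("ctx%02d", 1:68), letters[1:9]))
  sub <- matrix(rnorm(115 * 7), 115, 7,
                dimnames = list(sprintf("sub%03d", 1:115), letters[1:7]))
  v <- assembleStructural(cort, sub)
  expect_length(v, 1417L)
  expect_equal(names(v)[1], "ctx01.a")

  shuf <- cort[sample(68), ]
  expect_identical(assembleStructural(shuf, sub), v)

  one <- cort[1, , drop = FALSE]
  expect_length(assembleStructural(one, sub[0, , drop = FALSE]), 9L)

  cort_na <- cort; cort_na["ctx05", 3] <- NA
  expect_error(assembleStructural(cort_na, sub), "ctx05")
})

test_that("standardizer uses the population convention and train-only parameters", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- fitStandardizer(X)
  Xs <- applyStandardizer(s, X)
  expect_equal(Xs[, "a"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(Xs[, "b"], c(0, 0, 0))
  # held-out row at the training mean maps to zero
  expect_equal(unname(applyStandardizer(s, rbind(c(2, 5)))), rbind(c(0, 0)))

  set.seed(4)
  Xtr <- matrix(rnorm(50 * 6), 50, 6)
  s2 <- fitStandardizer(Xtr)
  Z <- applyStandardizer(s2, Xtr)
  expect_equal(unname(colMeans(Z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(colMeans(Z^2)), rep(1, 6), tolerance = 1e-10)
})

test_that("RFE ranking is an elimination-order permutation", {
  set.seed(5)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rep(c("autism", "td"), 20)
  r <- rfeRank(X, y, step = 1)
  expect_setequal(unname(r$rank), 1:12)
  expect_true(all(selectTopK(r, 12)))
  expect_equal(sum(selectTopK(r, 4)), 4L)
  expect_error(selectTopK(r, 13), "exceeds")

  r2 <- rfeRank(X, y, step = 0.25)
  expect_setequal(unname(r2$rank), 1:12)
})

test_that("RFE recovers planted signal features", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 500L; p <- 100L
    y <- rep(c("autism", "td"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1:5] <- X[, 1:5] + ifelse(y == "autism", 1, -1)  # d = 2
    Xs <- applyStandardizer(fitStandardizer(X), X)
    mask <- selectTopK(rfeRank(Xs, y), 5)
    sum(which(mask) <= 5)
  }, numeric(1))
  expect_true(all(hits >= 4))
  expect_gte(mean(hits), 4.8)
})

test_that("feature sets concatenate blocks in fmri/smri/pheno order", {
  n <- 4L
  ids <- sprintf("p%d", 1:n)
  fmri <- matrix(rnorm(n * 4000), n, 4000,
                 dimnames = list(ids, sprintf("e%d", 1:4000)))
  smri <- matrix(rnorm(n * 800), n, 800,
                 dimnames = list(ids, sprintf("s%d", 1:800)))
  ph <- matrix(rnorm(n * 6), n, 6,
               dimnames = list(ids, c("age", "sex", "fiq", "num", "pec", "rat")))
  expect_equal(nrow(assembleFeatureSet("f+p", fmri = fmri, pheno = ph)), 4006L)
  expect_equal(nrow(assembleFeatureSet("s", smri = smri)), 800L)
  se <- assembleFeatureSet("s+f+p", fmri = fmri, smri = smri, pheno = ph)
  expect_equal(nrow(se), 4806L)
  expect_equal(featureModality(se),
               rep(c("fmri", "smri", "pheno"), c(4000, 800, 6)))
  expect_equal(rownames(featureValues(se)), ids)

  bad <- smri; rownames(bad) <- rev(ids)
  expect_error(assembleFeatureSet("s+f", fmri = fmri, smri = bad),
               "do not match")
  expect_error(assembleFeatureSet("f"), "fmri")
})

test_that("test-row labels cannot influence the fitted pipeline", {
  co <- tinyCohort(seed = 13)
  blocks <- connectomeBench:::cohortFeatureBlocks(co)
  y <- as.character(phenotypes(co)$label)
  n <- length(y)
  train <- 1:30
  test <- setdiff(seq_len(n), train)
  y_perm <- y
  y_perm[test] <- sample(y[test])
  fb1 <- connectomeBench:::buildFoldFeatures(blocks, "s+f", train, y, 30, 15)
  fb2 <- connectomeBench:::buildFoldFeatures(blocks, "s+f", train, y_perm, 30, 15)
  expect_identical(fb1$pipes$fmri$std, fb2$pipes$fmri$std)
  expect_identical(fb1$pipes$fmri$ranking, fb2$pipes$fmri$ranking)
  expect_identical(fb1$pipes$smri$ranking, fb2$pipes$smri$ranking)
  expect_identical(fb1$X, fb2$X)
})
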