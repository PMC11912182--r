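test_that("stratified folds spread every (site,label) cell within one", {
  # 10 samples, one site, balanced labels, k = 5: one of each per fold
  fp <- makeStratifiedFolds(rep(c("autism", "td"), 5), rep("A", 10),
                            k = 5, seed = 1)
  tab <- table(foldAssignments(fp), rep(c("autism", "td"), 5))
  expect_true(all(tab == 1))

  # full-scale composition: expand the 20-site table into label vectors
  st <- abideSiteTable()
  sites <- rep(st$site, st$n_autism + st$n_td)
  labels <- unlist(mapply(function(a, t) c(rep("autism", a), rep("td", t)),
                          st$n_autism, st$n_td, SIMPLIFY = FALSE))
  fp2 <- makeStratifiedFolds(labels, sites, k = 5, seed = 2)
  fold <- foldAssignments(fp2)
  expect_equal(length(fold), 870L)
  expect_true(all(abs(table(fold) - 174) <= 1))
  for (s in unique(sites)) for (l in c("autism", "td")) {
    cell <- fold[sites == s & labels == l]
    if (!length(cell)) next
    cnt <- tabulate(cell, 5)
    expect_lte(max(abs(cnt - length(cell) / 5)), 1)
  }
  # deterministic given the seed; different under another seed
  expect_identical(fold,
                   foldAssignments(makeStratifiedFolds(labels, sites, 5, 2)))
  expect_false(identical(fold,
                         foldAssignments(makeStratifiedFolds(labels, sites, 5, 3))))
  expect_error(makeStratifiedFolds(c("autism", "td"), c("A", "A"), k = 5),
               "fewer samples")
})

test_that("accuracy and AUC match brute-force enumeration", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(c(0.2, 0.2), c(1, 0)), 0.5)
  set.seed(51)
  scores <- round(rnorm(30), 1)  # rounded to force ties
  y <- rbinom(30, 1, 0.5)
  pos <- which(y == 1); neg <- which(y == 0)
  oracle <- mean(vapply(pos, function(i)
    mean((scores[i] > scores[neg]) + 0.5 * (scores[i] == scores[neg])),
    numeric(1)))
  expect_equal(rocAUC(scores, y), oracle)
  expect_error(rocAUC(scores, rep(1, 30)), "single class")
  expect_equal(classificationAccuracy(c("autism", "td"), c("autism", "autism")),
               0.5)
})

test_that("paired t and chi-squared statistics match closed forms", {
  expect_equal(pairedTTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- pairedTTest(1:5, rep(0, 5))
  expect_equal(r$t, 4.242641, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0132355996, tolerance = 1e-8)
  expect_error(pairedTTest(1, 2), "pairs")

  # contingency ((50,10),(10,50)) via constructed correctness patterns
  labels <- rep("td", 120)
  ca <- rep(c(FALSE, FALSE, TRUE, TRUE), c(50, 10, 10, 50))
  cb <- rep(c(FALSE, TRUE, FALSE, TRUE), c(50, 10, 10, 50))
  pa <- ifelse(ca, "td", "autism")
  pb <- ifelse(cb, "td", "autism")
  r2 <- chiSquaredBest(pa, pb, labels)
  hand <- 120 * (50 * 50 - 10 * 10)^2 / (60 * 60 * 60 * 60)
  expect_equal(r2$statistic, hand, tolerance = 1e-12)
})

test_that("cross-validation scores every sample exactly once, without leakage", {
  co <- tinyCohort(seed = 61)
  ph <- phenotypes(co)
  fp <- makeStratifiedFolds(ph$label, ph$site, k = 5, seed = 3)
  r <- runCV("svm", "s+f", fp, co, k_fmri = 30, k_smri = 15, seed = 11)
  pr <- predictions(r)
  expect_identical(as.character(pr$id), as.character(ph$id))
  expect_true(all(pr$pred %in% c("autism", "td")))
  expect_equal(r@accuracy,
               classificationAccuracy(pr$pred, pr$label))
  expect_equal(nrow(r@perFold), 5L)
  # strongly separable cohort: recovery near ceiling
  expect_gte(r@accuracy, 0.9)

  # another fold seed: different memberships, still exactly one
  # prediction per sample
  fp2 <- makeStratifiedFolds(ph$label, ph$site, k = 5, seed = 4)
  expect_false(identical(foldAssignments(fp), foldAssignments(fp2)))
  r2 <- runCV("svm", "s+f", fp2, co, k_fmri = 30, k_smri = 15, seed = 11)
  expect_identical(as.character(predictions(r2)$id), as.character(ph$id))
})

test_that("pooled accuracy is non-decreasing in the planted effect size", {
  accs <- vapply(c(0, 1, 2.5), function(d) {
    mean(vapply(1:3, function(s) {
      co <- tinyCohort(seed = 100 + s, d = d)
      ph <- phenotypes(co)
      fp <- makeStratifiedFolds(ph$label, ph$site, k = 5, seed = s)
      runCV("svm", "s", fp, co, k_smri = 20, seed = s)@accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_lt(accs[1], 0.75)
  expect_gt(accs[3], 0.85)
})

test_that("the chance-control permutation balances sites and preserves the multiset", {
  st <- abideSiteTable(0.2)
  sites <- rep(st$site, st$n_autism + st$n_td)
  labels <- unlist(mapply(function(a, t) c(rep("autism", a), rep("td", t)),
                          st$n_autism, st$n_td, SIMPLIFY = FALSE))
  perm <- nullPermutation(labels, sites, seed = 31)
  expect_equal(sort(perm), sort(labels))      # a true permutation
  expect_identical(perm, nullPermutation(labels, sites, seed = 31))
  # per-site autism share within one of proportional
  p_global <- mean(labels == "autism")
  for (s in unique(sites)) {
    n_s <- sum(sites == s)
    expect_lte(abs(sum(perm[sites == s] == "autism") - p_global * n_s), 1)
  }
})

test_that("nested cross-validation trains 25 models on disjoint inner splits", {
  co <- tinyCohort(seed = 62)
  ph <- phenotypes(co)
  fp <- makeStratifiedFolds(ph$label, ph$site, k = 5, seed = 5)
  nv <- runNestedCV("svm", "s", fp, co, k_smri = 20, seed = 6,
                    inner_seed = 7)
  expect_equal(sum(lengths(nv@models)), 25L)
  fold <- foldAssignments(fp)
  for (f in 1:5) {
    test_ids <- ph$id[fold == f]
    for (inner in nv@models[[f]]) {
      expect_length(intersect(inner$train_ids, test_ids), 0)
      expect_length(intersect(inner$val_ids, test_ids), 0)
      expect_length(intersect(inner$train_ids, inner$val_ids), 0)
      expect_setequal(inner$test_ids, test_ids)
    }
    expect_equal(dim(nv@innerVotes[[f]]), c(5L, sum(fold == f)))
  }
  pr <- predictions(nv)
  expect_identical(as.character(pr$id), as.character(ph$id))
  # voted label always carries >= 3 of the 5 inner votes
  for (f in 1:5) {
    votes <- nv@innerVotes[[f]]
    voted <- pr$pred[fold == f]
    expect_true(all(colSums(votes == rep(voted, each = 5)) >= 3))
  }
})
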