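#' Site x label stratified test folds
#'
#' Splits the cohort into k folds so that every (site, label) cell is
#' spread across folds as evenly as possible (per-fold cell counts within
#' one of cell/k). Members of each cell are shuffled by the seed and dealt
#' round-robin starting at the currently smallest fold, which achieves the
#' guarantee deterministically. The plan is meant to be fixed once per
#' experiment and shared by all architectures and feature modes, so paired
#' comparisons are valid.
#'
#' @param labels,sites per-sample label and site vectors.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return a [FoldPlan-class].
#' @export
makeStratifiedFolds <- function(labels, sites, k = 5L, seed = 1L) {
  n <- length(labels)
  stopifnot2(length(sites) == n, "labels and sites must align")
  stopifnot2(k >= 2L, "k must be >= 2")
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  fold <- integer(n)
  sizes <- integer(k)
  cells <- split(seq_len(n), list(site = as.character(sites),
                                  label = as.character(labels)), drop = TRUE)
  cells <- cells[order(names(cells))]
  withSeed(seed, {
    for (cell in cells) {
      members <- if (length(cell) > 1L) sample(cell) else cell
      ord <- order(sizes, seq_len(k))   # smallest fold first, ties by index
      for (m in seq_along(members)) {
        f <- ord[(m - 1L) %% k + 1L]
        fold[members[m]] <- f
        sizes[f] <- sizes[f] + 1L
      }
    }
  })
  strata <- as.data.frame(table(fold = fold, site = as.character(sites),
                                label = as.character(labels)))
  strata <- strata[strata$Freq > 0 | TRUE, ]
  methods::new("FoldPlan", fold = fold, k = as.integer(k),
               seed = as.integer(seed), strata = strata)
}

#' Classification accuracy
#' @param preds,labels aligned prediction and truth vectors.
#' @export
classificationAccuracy <- function(preds, labels) {
  stopifnot2(length(preds) == length(labels), "length mismatch")
  mean(as.character(preds) == as.character(labels))
}

#' Area under the ROC curve
#'
#' AUC as the probability that a random positive (autism) outranks a
#' random negative, ties counted one half (rank/Wilcoxon formula).
#'
#' @param scores numeric scores, higher = more autism-like.
#' @param labels binary labels (`"autism"`/`"td"` or 0/1).
#' @export
rocAUC <- function(scores, labels) {
  y <- labelTo01(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired t-test on per-fold metrics
#'
#' Dependent-samples t-test on the differences of two aligned metric
#' vectors (e.g. per-fold test accuracies of two models). Identical
#' vectors (all differences zero) return `p = 1` by convention.
#'
#' @param a,b aligned numeric vectors (>= 2 pairs).
#' @return list with `t`, `df`, `p`.
#' @export
pairedTTest <- function(a, b) {
  stopifnot2(length(a) == length(b) && length(a) >= 2L,
             "need at least 2 aligned pairs")
  d <- a - b
  if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1))
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Chi-squared comparison of two models' correctness patterns
#'
#' Builds the 2 x 2 contingency table of correct/incorrect predictions of
#' two models on the same samples and applies the chi-squared test
#' (without continuity correction).
#'
#' @param pred_a,pred_b predicted labels of the two models.
#' @param labels true labels.
#' @return list with `statistic`, `p`, `table`.
#' @export
chiSquaredBest <- function(pred_a, pred_b, labels) {
  ca <- factor(as.character(pred_a) == as.character(labels), c(FALSE, TRUE))
  cb <- factor(as.character(pred_b) == as.character(labels), c(FALSE, TRUE))
  tab <- table(a_correct = ca, b_correct = cb)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value, table = tab)
}

#' Site-balanced label permutation for chance controls
#'
#' Draws a permutation of the label multiset in which every site receives
#' a share of each class proportional to its size (largest-remainder
#' allocation, exact in the class totals), assigned randomly within site.
#' A *global* label permutation leaves randomly uneven per-site label
#' rates, and in a multi-site cohort with per-site feature offsets any
#' site-aware classifier can learn those rates and beat 0.5 without any
#' leakage; the balanced permutation removes that genuine site-composition
#' association, so pooled accuracy on the permuted cohort estimates pure
#' chance (plus the global class imbalance).
#'
#' @param labels,sites per-sample label and site vectors.
#' @param seed permutation seed.
#' @return character vector: permuted labels, same multiset as `labels`.
#' @export
nullPermutation <- function(labels, sites, seed = 1L) {
  labels <- as.character(labels)
  sites <- as.character(sites)
  n <- length(labels)
  classes <- sort(unique(labels))
  stopifnot2(length(classes) == 2L, "labels must be binary")
  n_pos <- sum(labels == classes[1L])
  site_n <- table(sites)
  # largest-remainder apportionment of the positive class across sites
  quota <- as.numeric(site_n) * n_pos / n
  base <- floor(quota)
  rem <- n_pos - sum(base)
  extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1L
  names(base) <- names(site_n)
  out <- character(n)
  withSeed(seed, {
    for (s in names(site_n)) {
      idx <- which(sites == s)
      lab <- c(rep(classes[1L], base[[s]]),
               rep(classes[2L], length(idx) - base[[s]]))
      out[idx] <- if (length(lab) > 1L) sample(lab) else lab
    }
  })
  out
}

# ---- feature pipeline (per training split) -------------------------------

#' Raw modality blocks of a cohort
#'
#' Vectorizes every participant's connectivity matrix (upper triangle,
#' [edgeIndex()] order), and returns the edge, structural and phenotype
#' blocks aligned to the phenotype table's row order.
#' @param cohort a [Cohort-class].
#' @return list with `edges`, `struct`, `pheno` matrices and `edge_index`.
#' @export
cohortFeatureBlocks <- function(cohort) {
  ph <- phenotypes(cohort)
  fc <- fcMatrices(cohort)
  if (length(fc) == 0L)
    fc <- lapply(cohort@timeseries, pearsonFC)
  n_roi <- nrow(fc[[1L]])
  ei <- edgeIndex(n_roi)
  edges <- t(vapply(ph$id, function(id) vectorizeUpper(fc[[id]])$values,
                    numeric(nrow(ei))))
  rownames(edges) <- ph$id
  ph_block <- phenoFeatureBlock(ph)
  st <- structMatrix(cohort)
  list(edges = edges, struct = st, pheno = ph_block, edge_index = ei)
}

# Fit standardizer + RFE on training rows only; return the standardized,
# selected block for all rows plus the fitted pipeline.
fitModalityPipeline <- function(block, train_idx, y_train, k, rfe_step = 0.1) {
  std <- fitStandardizer(block[train_idx, , drop = FALSE])
  Xtr <- applyStandardizer(std, block[train_idx, , drop = FALSE])
  if (k >= ncol(block)) {
    mask <- rep(TRUE, ncol(block))
    ranking <- NULL
  } else {
    ranking <- rfeRank(Xtr, y_train, step = rfe_step)
    mask <- selectTopK(ranking, k)
  }
  X_all <- applyStandardizer(std, block)[, mask, drop = FALSE]
  list(X = X_all, std = std, ranking = ranking, mask = mask)
}

# Assemble the requested feature mode with train-only fitting.
buildFoldFeatures <- function(blocks, mode, train_idx, y, k_fmri, k_smri,
                              rfe_step = 0.1) {
  want <- strsplit(mode, "+", fixed = TRUE)[[1L]]
  y_tr <- y[train_idx]
  fmri <- smri <- phn <- NULL
  pipes <- list()
  if ("f" %in% want) {
    pipes$fmri <- fitModalityPipeline(blocks$edges, train_idx, y_tr, k_fmri,
                                      rfe_step)
    fmri <- pipes$fmri$X
  }
  if ("s" %in% want) {
    pipes$smri <- fitModalityPipeline(blocks$struct, train_idx, y_tr, k_smri,
                                      rfe_step)
    smri <- pipes$smri$X
  }
  if ("p" %in% want) {
    std <- fitStandardizer(blocks$pheno[train_idx, , drop = FALSE])
    phn <- applyStandardizer(std, blocks$pheno)
    pipes$pheno <- list(std = std)
  }
  se <- assembleFeatureSet(mode, fmri = fmri, smri = smri, pheno = phn)
  list(X = featureValues(se), se = se, pipes = pipes)
}

trainOneModel <- function(architecture, X, y01, idx, spec, pheno) {
  tr <- idx$train; va <- idx$val
  ylab <- ifelse(y01 == 1L, "autism", "td")
  if (architecture %in% c("svm", "fcn", "ae_fcn")) {
    fn <- switch(architecture, svm = trainSVM, fcn = trainFCN,
                 ae_fcn = trainAEFCN)
    fn(X[tr, , drop = FALSE], ylab[tr], X[va, , drop = FALSE], ylab[va], spec)
  } else {
    n <- nrow(X)
    masks <- list(train = seq_len(n) %in% tr, val = seq_len(n) %in% va,
                  test = seq_len(n) %in% idx$test)
    if (architecture == "gcn")
      trainGCN(X, as.character(pheno$site), ylab, masks, spec)
    else trainEVGCN(X, pheno, ylab, masks, spec)
  }
}

scoreModel <- function(model, X, idx) {
  if (is(model, "GraphClassifier")) classScores(model, idx)
  else classScores(model, X[idx, , drop = FALSE])
}

selectedHyper <- function(model) {
  if (is(model, "SVMClassifier")) model@cost else model@selectedIteration
}

#' Five-fold cross-validation of one architecture on one feature set
#'
#' Per fold: one group is the test set, one the validation set (used only
#' to tune hyperparameters: C for the SVM, iteration count for the
#' networks), and the remaining three are the training set; groups rotate
#' so that every sample is scored exactly once by a model that never saw
#' it. Feature standardization and ridge-RFE selection are re-fit inside
#' every fold on the training rows only.
#'
#' @param architecture `"svm"`, `"fcn"`, `"ae_fcn"`, `"gcn"`, `"ev_gcn"`.
#' @param mode feature mode (`"s"`, `"s+p"`, `"f"`, `"f+p"`, `"s+f"`,
#'   `"s+f+p"`).
#' @param fold_plan a [makeStratifiedFolds()] plan with k = 5 (any k >= 3
#'   is accepted; the validation group is the next fold cyclically).
#' @param cohort a [Cohort-class].
#' @param k_fmri,k_smri number of edges / structural features kept by RFE.
#' @param rfe_step RFE elimination fraction per iteration.
#' @param spec_args list of [modelSpec()] overrides (training budget etc.).
#' @param seed master seed for per-fold model seeds.
#' @return a [CVResult-class].
#' @export
runCV <- function(architecture, mode, fold_plan, cohort,
                  k_fmri = 4000L, k_smri = 800L, rfe_step = 0.1,
                  spec_args = list(), seed = 1L) {
  ph <- phenotypes(cohort)
  y01 <- labelTo01(as.character(ph$label))
  blocks <- cohortFeatureBlocks(cohort)
  k <- fold_plan@k
  stopifnot2(k >= 3L, "cross-validation needs k >= 3 (train/val/test groups)")
  fold <- foldAssignments(fold_plan)
  seeds <- deriveSeeds(seed, k)
  n <- length(y01)
  pred <- character(n); score <- numeric(n)
  perFold <- NULL
  for (f in seq_len(k)) {
    test <- which(fold == f)
    val <- which(fold == (f %% k) + 1L)
    train <- setdiff(seq_len(n), c(test, val))
    if (length(intersect(train, test)) || length(intersect(val, test)))
      stop("internal error: train/test overlap", call. = FALSE)
    fb <- buildFoldFeatures(blocks, mode, train, ifelse(y01 == 1L, "autism", "td"),
                            k_fmri, k_smri, rfe_step)
    spec <- do.call(modelSpec, c(list(architecture, ncol(fb$X),
                                      seed = seeds[f]), spec_args))
    model <- trainOneModel(architecture, fb$X, y01,
                           list(train = train, val = val, test = test),
                           spec, ph)
    sc_te <- scoreModel(model, fb$X, test)
    sc_va <- scoreModel(model, fb$X, val)
    pred[test] <- ifelse(sc_te[, "autism"] > sc_te[, "td"], "autism", "td")
    score[test] <- sc_te[, "autism"]
    va_pred <- ifelse(sc_va[, "autism"] > sc_va[, "td"], "autism", "td")
    perFold <- rbind(perFold, data.frame(
      fold = f,
      val_accuracy = classificationAccuracy(va_pred,
                                            ifelse(y01[val] == 1L, "autism", "td")),
      test_accuracy = classificationAccuracy(pred[test],
                                             ifelse(y01[test] == 1L, "autism", "td")),
      hyper = selectedHyper(model)))
  }
  labels <- ifelse(y01 == 1L, "autism", "td")
  methods::new("CVResult", architecture = architecture, featureMode = mode,
               predictions = S4Vectors::DataFrame(
                 id = ph$id, fold = fold, label = labels, pred = pred,
                 score = score),
               perFold = perFold,
               accuracy = classificationAccuracy(pred, labels),
               auc = rocAUC(score, labels))
}

# Per-architecture hyperparameter handling for nested CV: phase 1 trains
# with the full grid and reports validation accuracy per grid point; phase
# 2 retrains with the selected point.
gridAccuracies <- function(architecture, model, spec) {
  if (architecture == "svm") attr(model, "grid_acc")
  else {
    h <- model@history
    stats::setNames(h$val_accuracy, h$iteration)
  }
}

#' Nested five-fold cross-validation for max-voting ensembles
#'
#' In each outer fold the outer-test group is held out and the remaining
#' samples are re-split into five inner groups with the same site x label
#' stratification. The five inner models provide validation accuracies
#' whose grid average selects one hyperparameter per outer fold (C for the
#' SVM, iteration count for the networks); the five inner models retrained
#' at the selected value then vote on the outer test set. This trains
#' 5 x 5 = 25 models per architecture, and no outer-test sample ever
#' enters an inner training or validation split.
#'
#' @inheritParams runCV
#' @param inner_seed seed for the inner fold splits.
#' @return a [NestedCVResult-class].
#' @export
runNestedCV <- function(architecture, mode, fold_plan, cohort,
                        k_fmri = 4000L, k_smri = 800L, rfe_step = 0.1,
                        spec_args = list(), seed = 1L, inner_seed = 100L) {
  ph <- phenotypes(cohort)
  y01 <- labelTo01(as.character(ph$label))
  labels <- ifelse(y01 == 1L, "autism", "td")
  blocks <- cohortFeatureBlocks(cohort)
  k <- fold_plan@k
  fold <- foldAssignments(fold_plan)
  n <- length(y01)
  seeds <- deriveSeeds(seed, k * k)
  iseeds <- deriveSeeds(inner_seed, k)
  pred <- character(n); score <- numeric(n)
  innerVotes <- vector("list", k); models <- vector("list", k)
  perOuter <- NULL
  for (f in seq_len(k)) {
    test <- which(fold == f)
    rest <- setdiff(seq_len(n), test)
    iplan <- makeStratifiedFolds(labels[rest], as.character(ph$site)[rest],
                                 k = k, seed = iseeds[f])
    ifold <- foldAssignments(iplan)
    phase1 <- vector("list", k)
    feats <- vector("list", k)
    for (g in seq_len(k)) {
      ival <- rest[ifold == g]
      itrain <- setdiff(rest, ival)
      if (length(intersect(c(itrain, ival), test)))
        stop("internal error: outer-test leakage into inner split",
             call. = FALSE)
      fb <- buildFoldFeatures(blocks, mode, itrain, labels, k_fmri, k_smri,
                              rfe_step)
      feats[[g]] <- fb
      spec <- do.call(modelSpec, c(list(architecture, ncol(fb$X),
                                        seed = seeds[(f - 1L) * k + g]),
                                   spec_args))
      idx <- list(train = itrain, val = ival, test = test)
      phase1[[g]] <- list(
        model = trainInnerGrid(architecture, fb$X, y01, idx, spec, ph),
        spec = spec, idx = idx)
    }
    accs <- lapply(phase1, function(p1)
      gridAccuracies(architecture, p1$model, p1$spec))
    grid <- names(accs[[1L]])
    am <- matrix(vapply(accs, function(a) a[grid], numeric(length(grid))),
                 nrow = length(grid))
    sel <- grid[which.max(rowMeans(am))]
    inner_models <- vector("list", k)
    vote_lab <- matrix("", k, length(test))
    vote_sc <- matrix(0, k, length(test))
    for (g in seq_len(k)) {
      m <- retrainAtHyper(architecture, feats[[g]]$X, y01, phase1[[g]]$idx,
                          phase1[[g]]$spec, ph, sel, phase1[[g]]$model)
      inner_models[[g]] <- list(
        model = m,
        test_X = feats[[g]]$X[test, , drop = FALSE],
        test_ids = ph$id[test],
        train_ids = ph$id[phase1[[g]]$idx$train],
        val_ids = ph$id[phase1[[g]]$idx$val])
      sc <- scoreModel(m, feats[[g]]$X, test)
      vote_lab[g, ] <- ifelse(sc[, "autism"] > sc[, "td"], "autism", "td")
      vote_sc[g, ] <- sc[, "autism"]
    }
    voted <- maxVote(vote_lab, scores = vote_sc)
    pred[test] <- voted
    score[test] <- colMeans(vote_sc)
    innerVotes[[f]] <- vote_lab
    models[[f]] <- inner_models
    perOuter <- rbind(perOuter, data.frame(fold = f, hyper = sel))
  }
  methods::new("NestedCVResult", architecture = architecture,
               featureMode = mode,
               predictions = S4Vectors::DataFrame(
                 id = ph$id, fold = fold, label = labels, pred = pred,
                 score = score),
               innerVotes = innerVotes, models = models, perOuter = perOuter,
               accuracy = classificationAccuracy(pred, labels),
               auc = rocAUC(score, labels))
}

# Phase 1: one training pass exposing the whole hyperparameter grid.
trainInnerGrid <- function(architecture, X, y01, idx, spec, pheno) {
  if (architecture == "svm") {
    ylab <- ifelse(y01 == 1L, "autism", "td")
    tr <- idx$train; va <- idx$val
    gamma <- 1 / (ncol(X) * max(stats::var(as.vector(X[tr, , drop = FALSE])), 1e-12))
    yf <- factor(ylab[tr], levels = c("td", "autism"))
    accs <- vapply(spec$C_grid, function(C) {
      fit <- e1071::svm(x = X[tr, , drop = FALSE], y = yf, kernel = "radial",
                        gamma = gamma, cost = C, scale = FALSE)
      mean(as.character(predict(fit, X[va, , drop = FALSE])) == ylab[va])
    }, numeric(1L))
    structure(list(), grid_acc = stats::setNames(accs, spec$C_grid))
  } else {
    trainOneModel(architecture, X, y01, idx, spec, pheno)
  }
}

# Phase 2: retrain with the selected hyperparameter fixed.
retrainAtHyper <- function(architecture, X, y01, idx, spec, pheno, sel,
                           phase1_model) {
  if (architecture == "svm") {
    spec$C_grid <- as.numeric(sel)
    trainOneModel(architecture, X, y01, idx, spec, pheno)
  } else {
    it <- as.integer(sel)
    spec$epochs_max <- it
    spec$checkpoint_every <- it
    trainOneModel(architecture, X, y01, idx, spec, pheno)
  }
}
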