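#' Desk-scale recovery experiment on a planted synthetic cohort
#'
#' Runs the package's standard end-to-end recovery study: a 20-site
#' cohort at 0.69 scale (580 participants, 270 autism), a 64-ROI atlas
#' (2016 connectivity edges), 203 structural features, 50 planted edges
#' and 20 planted structural features at a standardized effect size of
#' 1.5. It measures, from scratch:
#'
#' * pooled 5-fold cross-validated accuracy and AUC of all five
#'   architectures on the `s+f` feature set (500 edges + 100 structural
#'   features kept by ridge-RFE per fold);
#' * the pooled accuracy of the same pipeline on a label-permuted copy of
#'   the cohort (chance control; the permutation is site-balanced, see
#'   [nullPermutation()]);
#' * max-voting nested cross-validation (SVM, structural features) over
#'   five fold-plan seeds, compared with the mean accuracy of its 25
#'   inner models;
#' * the recall of the 50 planted edges among the top-50 SmoothGrad
#'   saliency features of an FCN trained on connectivity features.
#'
#' All randomness is derived from `seed`. Network training budgets use a
#' 100-epoch grid with checkpoints every 10 epochs.
#'
#' @param seed master seed.
#' @param parts character subset of
#'   `c("cv", "null", "voting", "saliency")` to run.
#' @param epochs_max training budget for the network architectures.
#' @param verbose print progress.
#' @return list with elements `cv` (per-architecture accuracy/AUC),
#'   `null_accuracy`, `voting` (per-seed voted and inner-mean accuracy),
#'   `saliency_recall`, and the `conditions` used.
#' @export
recoveryExperiment <- function(seed = 1L,
                               parts = c("cv", "null", "voting", "saliency"),
                               epochs_max = 100L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seeds <- deriveSeeds(seed, 20L)
  cfg <- generationConfig(n_rois = 64L, site_table = abideSiteTable(0.69),
                          n_informative_edges = 50L,
                          n_informative_struct = 20L,
                          n_cortical = 14L, n_noncortical = 11L,
                          effect_size_d = 1.5, seed = seeds[1L])
  co <- generateCohort(cfg)
  ph <- phenotypes(co)
  fp <- makeStratifiedFolds(ph$label, ph$site, k = 5L, seed = seeds[2L])
  sa <- list(epochs_max = as.integer(epochs_max))
  out <- list(conditions = list(
    n = nrow(ph), n_autism = sum(ph$label == "autism"),
    n_edges = cfg$n_rois * (cfg$n_rois - 1L) / 2,
    n_struct = cfg$n_cortical * 9L + cfg$n_noncortical * 7L,
    effect_size_d = cfg$effect_size_d,
    k_fmri = 500L, k_smri = 100L, seed = seed))

  if ("cv" %in% parts) {
    out$cv <- list()
    for (arch in c("svm", "fcn", "ae_fcn", "gcn", "ev_gcn")) {
      say("cv: ", arch)
      r <- runCV(arch, "s+f", fp, co, k_fmri = 500L, k_smri = 100L,
                 spec_args = if (arch == "svm") list() else sa,
                 seed = seeds[3L])
      out$cv[[arch]] <- list(accuracy = r@accuracy, auc = r@auc,
                             val_accuracy = mean(r@perFold$val_accuracy))
      say("  accuracy ", round(r@accuracy, 3))
    }
  }

  if ("null" %in% parts) {
    say("null: label-permuted cohort (site-balanced permutation)")
    co0 <- co
    co0@pheno$label <- nullPermutation(ph$label, ph$site, seed = seeds[4L])
    fp0 <- makeStratifiedFolds(co0@pheno$label, co0@pheno$site, k = 5L,
                               seed = seeds[5L])
    r0 <- runCV("svm", "s+f", fp0, co0, k_fmri = 500L, k_smri = 100L,
                seed = seeds[6L])
    out$null_accuracy <- r0@accuracy
    say("  accuracy ", round(r0@accuracy, 3))
  }

  if ("voting" %in% parts) {
    out$voting <- data.frame(seed_rep = 1:5, voted = NA_real_,
                             inner_mean = NA_real_)
    for (i in 1:5) {
      say("voting: seed replicate ", i)
      fpi <- makeStratifiedFolds(ph$label, ph$site, k = 5L,
                                 seed = seeds[6L + i])
      nv <- runNestedCV("svm", "s", fpi, co, k_smri = 100L,
                        seed = seeds[11L + i], inner_seed = seeds[16L])
      fold <- foldAssignments(fpi)
      inner_acc <- unlist(lapply(1:5, function(f) {
        truth <- as.character(ph$label)[fold == f]
        apply(nv@innerVotes[[f]], 1L, classificationAccuracy, labels = truth)
      }))
      out$voting$voted[i] <- nv@accuracy
      out$voting$inner_mean[i] <- mean(inner_acc)
    }
  }

  if ("saliency" %in% parts) {
    say("saliency: FCN on connectivity features")
    blocks <- cohortFeatureBlocks(co)
    fold <- foldAssignments(fp)
    y <- as.character(ph$label)
    tr <- which(fold <= 3L); va <- which(fold == 4L); te <- which(fold == 5L)
    fb <- buildFoldFeatures(blocks, "f", tr, y, 500L, 100L)
    spec <- modelSpec("fcn", ncol(fb$X), epochs_max = as.integer(epochs_max),
                      seed = seeds[17L])
    m <- trainFCN(fb$X[tr, ], y[tr], fb$X[va, ], y[va], spec)
    sal <- meanSaliency(m, fb$X[te, , drop = FALSE],
                        smoothGradConfig(seed = seeds[18L]))
    top <- topFeatures(sal, 50L)
    planted_ids <- blocks$edge_index$id[groundTruth(co)$planted_edge_ids]
    out$saliency_recall <- mean(planted_ids %in% top$feature_id)
    say("  top-50 planted recall ", out$saliency_recall)
  }
  out
}
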