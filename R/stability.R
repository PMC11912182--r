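# Stability pipeline: SmoothGrad saliency of the 5 inner models of each
# outer fold, per-participant SNR, repeated nested runs to wash out
# initialization bias.

#' Full feature-id universe of a cohort under a feature mode
#'
#' Saliency maps from models with different per-fold RFE selections are
#' compared in this common space (unselected features carry zero
#' saliency), so the SNR also penalizes selection instability.
#' @param cohort a [Cohort-class].
#' @param mode feature mode.
#' @export
fullFeatureIds <- function(cohort, mode) {
  blocks <- cohortFeatureBlocks(cohort)
  want <- strsplit(mode, "+", fixed = TRUE)[[1L]]
  c(if ("f" %in% want) blocks$edge_index$id,
    if ("s" %in% want) colnames(blocks$struct),
    if ("p" %in% want) colnames(blocks$pheno))
}

#' Per-participant saliency SNR from one nested cross-validation run
#'
#' For every participant, SmoothGrad saliency maps are generated from the
#' five inner models of the participant's outer fold (the models that
#' never trained on it), embedded into the full feature space, and reduced
#' to the participant's average SNR by [participantSNR()].
#'
#' @param nested a [NestedCVResult-class] (any differentiable
#'   architecture; svm is rejected by [smoothGrad()]).
#' @param full_ids common feature-id universe ([fullFeatureIds()]).
#' @param cfg a [smoothGradConfig()]; per-participant noise seeds are
#'   derived from `cfg$seed`.
#' @return named numeric vector: average SNR per participant id.
#' @export
nestedSaliencySNR <- function(nested, full_ids, cfg = smoothGradConfig()) {
  fold <- nested@predictions$fold
  ids <- nested@predictions$id
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  pseeds <- deriveSeeds(cfg$seed, length(ids))
  for (f in seq_along(nested@models)) {
    inner <- nested@models[[f]]
    test_ids <- inner[[1L]]$test_ids
    for (t in seq_along(test_ids)) {
      pid <- test_ids[t]
      pcfg <- cfg
      pcfg$seed <- pseeds[match(pid, ids)]
      stack <- matrix(0, length(inner), length(full_ids),
                      dimnames = list(NULL, full_ids))
      for (g in seq_along(inner)) {
        m <- inner[[g]]$model
        sal <- if (methods::is(m, "GraphClassifier"))
          smoothGrad(m, match(pid, ids), pcfg)
        else smoothGrad(m, inner[[g]]$test_X[t, ], pcfg)
        stack[g, names(sal)] <- sal
      }
      out[pid] <- participantSNR(stack)$average
    }
  }
  out
}

#' Saliency stability of one architecture across repeated nested runs
#'
#' Repeats the nested cross-validation pipeline `n_repeats` times (same
#' fold plan, different model initializations), computes each
#' participant's average saliency SNR per repeat, and pools them into a
#' [StabilityReport-class]. Architectures with consistently high SNR rely
#' on the same features across training-set variation.
#'
#' @inheritParams runNestedCV
#' @param n_repeats number of repeated nested runs (3 in the full design).
#' @param cfg a [smoothGradConfig()].
#' @param ... passed to [runNestedCV()] (`k_fmri`, `k_smri`, `spec_args`...).
#' @return a [StabilityReport-class].
#' @export
saliencyStability <- function(architecture, mode, fold_plan, cohort,
                              n_repeats = 3L, cfg = smoothGradConfig(),
                              seed = 1L, ...) {
  full_ids <- fullFeatureIds(cohort, mode)
  rseeds <- deriveSeeds(seed, n_repeats)
  cols <- NULL
  for (r in seq_len(n_repeats)) {
    nested <- runNestedCV(architecture, mode, fold_plan, cohort,
                          seed = rseeds[r], ...)
    cols <- cbind(cols, nestedSaliencySNR(nested, full_ids, cfg))
  }
  colnames(cols) <- paste0("repeat_", seq_len(n_repeats))
  stabilityHistogram(cols, architecture = architecture)
}

#' Mean SmoothGrad saliency over a set of participants
#'
#' Convenience reduction used to extract the globally most important
#' features of a trained model: the per-participant saliency maps are
#' averaged feature-wise.
#'
#' @param model a differentiable [TrainedClassifier-class].
#' @param X feature rows to explain (fcn/ae_fcn) or node indices
#'   (gcn/ev_gcn).
#' @param cfg a [smoothGradConfig()]; per-participant seeds derived from
#'   `cfg$seed`.
#' @return named numeric mean saliency vector.
#' @export
meanSaliency <- function(model, X, cfg = smoothGradConfig()) {
  graphModel <- methods::is(model, "GraphClassifier")
  n <- if (graphModel) length(X) else nrow(X)
  seeds <- deriveSeeds(cfg$seed, n)
  acc <- NULL
  for (t in seq_len(n)) {
    pcfg <- cfg; pcfg$seed <- seeds[t]
    sal <- if (graphModel) smoothGrad(model, X[t], pcfg)
           else smoothGrad(model, X[t, ], pcfg)
    acc <- if (is.null(acc)) sal else acc + sal
  }
  acc / n
}
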