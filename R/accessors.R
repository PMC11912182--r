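#' @rdname Cohort-class
#' @export
setMethod("phenotypes", "Cohort", function(object) object@pheno)

#' @rdname Cohort-class
#' @export
setMethod("fcMatrices", "Cohort", function(object) object@fc)

#' @rdname Cohort-class
#' @export
setMethod("structMatrix", "Cohort", function(object) object@struct)

#' @rdname Cohort-class
#' @export
setMethod("groundTruth", "Cohort", function(object) object@groundTruth)

#' @rdname FoldPlan-class
#' @export
setMethod("foldAssignments", "FoldPlan", function(object) object@fold)

#' @rdname predictions
#' @export
setMethod("predictions", "CVResult", function(object) object@predictions)

#' @rdname predictions
#' @export
setMethod("predictions", "NestedCVResult", function(object) object@predictions)

setMethod("show", "Cohort", function(object) {
  ph <- object@pheno
  cat("Cohort with", nrow(ph), "participants from",
      length(unique(ph$site)), "sites\n")
  cat("  autism:", sum(ph$label == "autism"),
      " td:", sum(ph$label == "td"), "\n")
  if (length(object@fc))
    cat("  fc matrices:", nrow(object@fc[[1L]]), "x", ncol(object@fc[[1L]]), "\n")
  if (length(object@timeseries))
    cat("  time-series:", nrow(object@timeseries[[1L]]), "ROIs x",
        ncol(object@timeseries[[1L]]), "timepoints\n")
  if (ncol(object@struct))
    cat("  structural features:", ncol(object@struct), "\n")
  if (length(object@groundTruth))
    cat("  synthetic ground truth:",
        length(object@groundTruth$planted_edge_ids), "planted edges,",
        length(object@groundTruth$planted_struct_ids), "planted structural\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", length(object@fold), "samples in", object@k,
      "folds (seed", object@seed, ")\n")
  print(table(fold = object@fold))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s, features=%s]: pooled accuracy %.3f, AUC %.3f\n",
              object@architecture, object@featureMode,
              object@accuracy, object@auc))
})

setMethod("show", "NestedCVResult", function(object) {
  cat(sprintf(
    "NestedCVResult [%s, features=%s]: %d models, voted accuracy %.3f\n",
    object@architecture, object@featureMode,
    sum(lengths(object@models)), object@accuracy))
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport [%s]: %d participants, median SNR %.3f\n",
              object@architecture, nrow(object@snr),
              stats::median(object@snr$snr, na.rm = TRUE)))
})
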