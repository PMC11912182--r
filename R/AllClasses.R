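#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Cohort: a multi-site case/control neuroimaging cohort
#'
#' Container for one cohort: a participant phenotype table, per-participant
#' functional connectivity matrices (and optionally the ROI x time BOLD
#' series they were computed from), a participants x features structural
#' morphometry matrix, and -- for synthetic cohorts -- the generating ground
#' truth (planted feature indices and per-site offsets).
#'
#' @slot pheno [S4Vectors::DataFrame] with one row per participant, columns
#'   `id`, `site`, `label` (`"autism"`/`"td"`), `age`, `sex`, `fiq`, `num`,
#'   `pec`, `rat`.
#' @slot fc named list of square symmetric correlation matrices, one per
#'   participant (may be empty if only time-series are stored).
#' @slot timeseries named list of ROI x T matrices (may be empty).
#' @slot struct numeric matrix, participants x structural features.
#' @slot groundTruth list with elements `planted_edge_ids`,
#'   `planted_struct_ids`, `per_site_offsets`, or empty for real data.
#' @export
setClass("Cohort", slots = c(
  pheno = "DataFrame",
  fc = "list",
  timeseries = "list",
  struct = "matrix",
  groundTruth = "list"
))

setValidity("Cohort", function(object) {
  ph <- object@pheno
  need <- c("id", "site", "label", "age", "sex", "fiq", "num", "pec", "rat")
  if (!all(need %in% colnames(ph)))
    return(paste("pheno must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ph$id)) return("duplicate participant ids")
  if (!all(ph$label %in% c("autism", "td")))
    return("labels must be 'autism' or 'td'")
  n <- nrow(ph)
  if (length(object@fc) == 0L && length(object@timeseries) == 0L)
    return("at least one of fc/timeseries must be present")
  if (length(object@fc) > 0L && !setequal(names(object@fc), ph$id))
    return("fc names must match participant ids")
  if (nrow(object@struct) > 0L && nrow(object@struct) != n)
    return("struct must have one row per participant")
  num <- as.matrix(ph[, c("age", "fiq", "num", "pec", "rat")])
  if (!all(is.finite(num))) return("phenotype fields must be finite")
  TRUE
})

#' FoldPlan: site x label stratified assignment of samples to test folds
#'
#' @slot fold integer vector, fold index (1..k) per sample.
#' @slot k number of folds.
#' @slot seed seed the plan was drawn with.
#' @slot strata data.frame reporting per-fold (site, label) composition.
#' @export
setClass("FoldPlan", slots = c(
  fold = "integer", k = "integer", seed = "integer", strata = "data.frame"
))

setValidity("FoldPlan", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (!all(object@fold %in% seq_len(object@k)))
    return("fold indices must lie in 1..k")
  TRUE
})

#' TrainedClassifier: architecture-agnostic fitted scorer
#'
#' Virtual parent of all fitted classifiers. Every subclass honours the
#' [classScores()] contract (rows are probability-like and sum to one) and,
#' for differentiable architectures, the [inputGradient()] contract
#' (gradient of the autism-class pre-softmax score with respect to the
#' input features).
#'
#' @slot architecture one of `"svm"`, `"fcn"`, `"ae_fcn"`, `"gcn"`, `"ev_gcn"`.
#' @slot featureIds feature names the model was trained on.
#' @slot featureRange 2 x p matrix of per-feature training-set min/max
#'   (used by [smoothGrad()] to scale the perturbation noise).
#' @slot seed training seed.
#' @export
setClass("TrainedClassifier", representation("VIRTUAL",
  architecture = "character",
  featureIds = "character",
  featureRange = "matrix",
  seed = "integer"
))

#' @rdname TrainedClassifier-class
#' @slot fit underlying [e1071::svm] fit.
#' @slot calib intercept/slope of the logistic calibration of decision values.
#' @slot cost selected regularization parameter C.
#' @export
setClass("SVMClassifier", contains = "TrainedClassifier", slots = c(
  fit = "ANY", calib = "numeric", cost = "numeric"
))

#' @rdname TrainedClassifier-class
#' @slot params named list of weight matrices / bias vectors.
#' @slot spec the [modelSpec()] list the network was built from.
#' @slot history data.frame of checkpoint iteration vs validation accuracy.
#' @slot selectedIteration iteration count picked on the validation set.
#' @export
setClass("NetClassifier", contains = "TrainedClassifier", slots = c(
  params = "list", spec = "list", history = "data.frame",
  selectedIteration = "integer"
))

#' @rdname TrainedClassifier-class
#' @slot X full cohort feature matrix the transductive model was trained on.
#' @slot graph graph context: scaled Laplacian (gcn) or the phenotype
#'   encoding consumed by the pairwise association encoder (ev_gcn).
#' @slot masks list of train/val/test logical masks.
#' @slot scores cached class scores for all nodes.
#' @export
setClass("GraphClassifier", contains = "NetClassifier", slots = c(
  X = "matrix", graph = "list", masks = "list", scores = "matrix"
))

#' CVResult: pooled five-fold cross-validation result
#'
#' @slot architecture,featureMode experiment identifiers.
#' @slot predictions DataFrame: one row per sample with `id`, `fold`,
#'   `label`, `pred`, `score` (autism-class score, produced when that
#'   sample's fold was the test fold).
#' @slot perFold per-fold validation/test accuracy and selected
#'   hyperparameters.
#' @slot accuracy,auc pooled test-set metrics.
#' @export
setClass("CVResult", slots = c(
  architecture = "character", featureMode = "character",
  predictions = "DataFrame", perFold = "data.frame",
  accuracy = "numeric", auc = "numeric"
))

#' NestedCVResult: 5x5 nested cross-validation result
#'
#' @slot architecture,featureMode experiment identifiers.
#' @slot predictions DataFrame: per sample, the max-voted label over the 5
#'   inner models of its outer fold, plus mean autism score and true label.
#' @slot innerVotes list (one per outer fold) of inner-model label matrices.
#' @slot models list (outer fold -> list of 5 inner TrainedClassifiers).
#' @slot perOuter data.frame of selected hyperparameters per outer fold.
#' @slot accuracy,auc pooled voted metrics.
#' @export
setClass("NestedCVResult", slots = c(
  architecture = "character", featureMode = "character",
  predictions = "DataFrame", innerVotes = "list", models = "list",
  perOuter = "data.frame", accuracy = "numeric", auc = "numeric"
))

#' StabilityReport: per-participant saliency SNR across repeat-trained models
#'
#' @slot architecture model family the report describes.
#' @slot snr DataFrame: `id`, per-repeat SNR columns, `snr` (mean over
#'   repeats), `n_flagged` (features hitting the zero-std floor).
#' @slot histogram list with `breaks` and `counts` of the pooled SNR
#'   histogram.
#' @export
setClass("StabilityReport", slots = c(
  architecture = "character", snr = "DataFrame", histogram = "list"
))
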