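#' Class scores of a trained classifier
#'
#' Returns an n x 2 matrix of probability-like scores (columns `td`,
#' `autism`), each row summing to one. Feed-forward architectures score a
#' new feature matrix; transductive graph architectures score nodes of the
#' cohort they were trained on (`newdata` is then a node index vector, or
#' `NULL` for all nodes).
#'
#' @param object a [TrainedClassifier-class].
#' @param newdata feature matrix (svm/fcn/ae_fcn) or node indices
#'   (gcn/ev_gcn).
#' @param ... unused.
#' @return numeric matrix with columns `td`, `autism`.
#' @export
setGeneric("classScores", function(object, newdata = NULL, ...)
  standardGeneric("classScores"))

#' Gradient of the autism-class score with respect to the input features
#'
#' The gradient is taken on the pre-softmax score of the requested class
#' (softmax saturation suppresses gradients, so saliency is computed on
#' logits). For graph architectures the gradient is with respect to one
#' node's own feature row, with the population graph held fixed.
#'
#' @param object a differentiable [TrainedClassifier-class] (not svm).
#' @param x input feature row(s) (fcn/ae_fcn) or a node index (gcn/ev_gcn).
#' @param class `"autism"` (default) or `"td"`.
#' @param xnode for graph models, an optional replacement feature row for
#'   the node, used to evaluate gradients at perturbed inputs.
#' @param ... unused.
#' @return numeric vector (or matrix, one row per input row) of gradients.
#' @export
setGeneric("inputGradient", function(object, x, class = "autism", ...)
  standardGeneric("inputGradient"))

#' @rdname Cohort-class
#' @param object a Cohort.
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))

#' @rdname Cohort-class
#' @export
setGeneric("fcMatrices", function(object) standardGeneric("fcMatrices"))

#' @rdname Cohort-class
#' @export
setGeneric("structMatrix", function(object) standardGeneric("structMatrix"))

#' @rdname Cohort-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname FoldPlan-class
#' @param object a FoldPlan.
#' @export
setGeneric("foldAssignments", function(object) standardGeneric("foldAssignments"))

#' Pooled per-sample predictions of a (nested) cross-validation run
#' @param object a [CVResult-class] or [NestedCVResult-class].
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))
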