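#' Majority (max) voting over same-architecture models
#'
#' Each model's predicted label is one vote per sample; the output is the
#' modal label. With an even voter count a tie is broken by the mean
#' autism-class score when `scores` is supplied (>= 0.5 votes autism),
#' falling back to `"td"` when the scores tie exactly or are absent.
#'
#' @param votes m x n character matrix of labels (`"autism"`/`"td"`), one
#'   row per voting model.
#' @param scores optional m x n matrix of autism-class scores used for the
#'   tie-break.
#' @return character vector of n voted labels.
#' @export
maxVote <- function(votes, scores = NULL) {
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  if (nrow(votes) < 1L || length(votes) == 0L)
    stop("empty vote matrix", call. = FALSE)
  stopifnot2(all(votes %in% c("autism", "td")), "votes must be autism/td")
  n_aut <- colSums(votes == "autism")
  m <- nrow(votes)
  out <- ifelse(n_aut > m / 2, "autism", "td")
  tie <- n_aut == m / 2
  if (any(tie)) {
    if (!is.null(scores)) {
      ms <- colMeans(scores)[tie]
      out[tie] <- ifelse(ms > 0.5, "autism", "td")
    } else out[tie] <- "td"
  }
  out
}

#' EMMA: majority vote across the five architectures
#'
#' Combines the pooled cross-validated predictions of the five model
#' families (svm, fcn, ae_fcn, gcn, ev_gcn), each contributing exactly one
#' prediction per sample (produced when that sample's fold was the test
#' fold). With five voters and two classes no tie is possible; the winning
#' label always holds at least three votes.
#'
#' @param per_architecture_predictions 5 x n character matrix (row names
#'   are the architecture ids) or a list of five [CVResult-class] objects.
#' @return character vector of n voted labels.
#' @export
emmaVote <- function(per_architecture_predictions) {
  x <- per_architecture_predictions
  if (is.list(x) && !is.matrix(x)) {
    stopifnot2(all(vapply(x, function(r) methods::is(r, "CVResult"), TRUE)),
               "list input must contain CVResult objects")
    ids <- predictions(x[[1L]])$id
    x <- t(vapply(x, function(r) {
      p <- predictions(r)
      stopifnot2(identical(p$id, ids), "CVResults cover different samples")
      as.character(p$pred)
    }, character(length(ids))))
  }
  if (nrow(x) != 5L)
    stop("EMMA requires exactly five architecture prediction rows",
         call. = FALSE)
  maxVote(x)
}
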