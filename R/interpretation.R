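#' SmoothGrad configuration
#'
#' @param n_noisy number of noisy copies per participant (default 10).
#' @param noise_scale Gaussian noise SD as a fraction of each feature's
#'   training-set range (default 0.1; 0 reduces SmoothGrad to the plain
#'   gradient).
#' @param class class whose pre-softmax score is differentiated.
#' @param magnitude `"abs-of-mean"` (average the signed gradients over the
#'   noisy copies, then take absolute values; default) or `"mean-of-abs"`.
#' @param seed noise seed.
#' @export
smoothGradConfig <- function(n_noisy = 10L, noise_scale = 0.1,
                             class = "autism",
                             magnitude = c("abs-of-mean", "mean-of-abs"),
                             seed = 1L) {
  stopifnot2(n_noisy >= 1L, "n_noisy must be >= 1")
  stopifnot2(noise_scale >= 0, "noise_scale must be >= 0")
  structure(list(n_noisy = as.integer(n_noisy), noise_scale = noise_scale,
                 class = match.arg(class, c("autism", "td")),
                 magnitude = match.arg(magnitude), seed = as.integer(seed)),
            class = "SmoothGradConfig")
}

#' SmoothGrad saliency map for one participant
#'
#' Perturbs the participant's input with `n_noisy` elementwise Gaussian
#' noise draws (SD = `noise_scale` x per-feature training range), computes
#' the input gradient of the target-class pre-softmax score at each noisy
#' input, and aggregates by the magnitude rule. For a linear scorer the
#' result is exactly the absolute weight vector.
#'
#' @param model a differentiable [TrainedClassifier-class] (the svm is
#'   rejected: it exposes no input gradient).
#' @param x feature vector (fcn/ae_fcn) or node index (gcn/ev_gcn).
#' @param cfg a [smoothGradConfig()].
#' @return named numeric saliency vector aligned to the model's features.
#' @export
smoothGrad <- function(model, x, cfg = smoothGradConfig()) {
  if (model@architecture == "svm")
    stop("unsupported architecture: svm exposes no input gradient, ",
         "saliency analysis excludes it", call. = FALSE)
  rng <- model@featureRange["max", ] - model@featureRange["min", ]
  sdv <- cfg$noise_scale * rng
  graphModel <- methods::is(model, "GraphClassifier")
  x0 <- if (graphModel) model@X[as.integer(x), ] else as.numeric(x)
  p <- length(x0)
  withSeed(cfg$seed, {
    acc <- numeric(p)
    for (t in seq_len(cfg$n_noisy)) {
      eps <- stats::rnorm(p, 0, sdv)
      g <- if (graphModel)
        inputGradient(model, x, class = cfg$class, xnode = x0 + eps)
      else inputGradient(model, x0 + eps, class = cfg$class)
      acc <- acc + if (cfg$magnitude == "mean-of-abs") abs(g) else g
    }
    sal <- acc / cfg$n_noisy
    if (cfg$magnitude == "abs-of-mean") sal <- abs(sal)
    stats::setNames(sal, model@featureIds)
  })
}

#' Per-participant saliency signal-to-noise ratio
#'
#' Given the saliency maps of one participant from the five inner models
#' of its outer fold, computes the feature-wise mean, standard deviation
#' (sample, n-1) and SNR = mean/std, and the participant's average SNR
#' over features. Zero-std features have their std floored at 1e-12 and
#' are flagged; the participant average is taken over unflagged features
#' (NaN when every feature is flagged).
#'
#' @param stack models x features matrix of saliency maps (>= 2 rows;
#'   five in the nested-CV stability pipeline).
#' @return list with `average`, `per_feature` (mean/sd/snr/flagged) and
#'   `n_flagged`.
#' @export
participantSNR <- function(stack) {
  stack <- as.matrix(stack)
  if (nrow(stack) < 2L)
    stop("need at least 2 saliency maps", call. = FALSE)
  mu <- colMeans(stack)
  sd <- apply(stack, 2L, stats::sd)
  flagged <- sd < 1e-12
  snr <- mu / pmax(sd, 1e-12)
  list(average = mean(snr[!flagged]),
       per_feature = data.frame(mean = mu, sd = sd, snr = snr,
                                flagged = flagged,
                                row.names = colnames(stack)),
       n_flagged = sum(flagged))
}

#' Pool per-participant SNR values over repeats into a stability report
#'
#' The nested-CV stability pipeline is repeated (three times by default in
#' the full design) to wash out initialization bias; each participant's
#' SNR is averaged over the repeats and the pooled histogram is emitted
#' for cross-architecture comparison.
#'
#' @param snr_by_repeat participants x repeats numeric matrix (row names
#'   are participant ids); missing (NA) repeats are an error.
#' @param architecture label for the report.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return a [StabilityReport-class].
#' @export
stabilityHistogram <- function(snr_by_repeat, architecture = "fcn",
                               breaks = "Sturges") {
  m <- as.matrix(snr_by_repeat)
  if (anyNA(m)) stop("missing repeat values in SNR matrix", call. = FALSE)
  avg <- rowMeans(m)
  h <- graphics::hist(avg, breaks = breaks, plot = FALSE)
  df <- S4Vectors::DataFrame(id = rownames(m) %||% as.character(seq_len(nrow(m))),
                             m, snr = avg, check.names = FALSE)
  methods::new("StabilityReport", architecture = architecture, snr = df,
               histogram = list(breaks = h$breaks, counts = h$counts))
}

#' Nodal saliency strength of brain regions
#'
#' Assigns each connection's saliency to both incident regions and sums
#' per region, conserving mass: the strengths sum to twice the total edge
#' saliency.
#'
#' @param edge_saliency saliency value per edge.
#' @param edge_ids data.frame with columns `i`, `j` ([edgeIndex()]).
#' @param n_regions number of regions (default: max index referenced).
#' @return numeric vector of per-region strengths.
#' @export
nodalStrength <- function(edge_saliency, edge_ids, n_regions = NULL) {
  stopifnot2(length(edge_saliency) == nrow(edge_ids),
             "edge saliency and edge ids must align")
  n_regions <- n_regions %||% max(edge_ids$i, edge_ids$j)
  if (any(edge_ids$i > n_regions | edge_ids$j > n_regions |
            edge_ids$i < 1L | edge_ids$j < 1L))
    stop("edge references an unknown region", call. = FALSE)
  out <- numeric(n_regions)
  for (r in seq_len(n_regions))
    out[r] <- sum(edge_saliency[edge_ids$i == r]) +
      sum(edge_saliency[edge_ids$j == r])
  out
}

#' Z-score normalization with a floored scale
#'
#' Scores above 0 mark regions of above-average importance. A constant
#' input maps to all zeros.
#' @param scores numeric vector.
#' @export
zscoreMap <- function(scores) {
  s <- stats::sd(scores)
  if (!is.finite(s) || s < 1e-12) return(scores * 0)
  (scores - mean(scores)) / s
}

#' Top-k features by mean saliency
#'
#' Descending by saliency, deterministic tie-break by feature id.
#' @param mean_saliency named numeric vector.
#' @param k number of features to return (default 100).
#' @return data.frame with `feature_id`, `saliency`, `rank`.
#' @export
topFeatures <- function(mean_saliency, k = 100L) {
  stopifnot2(k <= length(mean_saliency), "k exceeds the feature count")
  ids <- names(mean_saliency) %||% sprintf("f%d", seq_along(mean_saliency))
  ord <- order(-mean_saliency, ids)
  data.frame(feature_id = ids[ord][seq_len(k)],
             saliency = unname(mean_saliency[ord][seq_len(k)]),
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Feature distributions across TP/TN/FP/FN prediction groups
#'
#' Partitions the cohort by the pooled cross-validated prediction: true
#' positive (correctly classified autism), true negative (correctly
#' classified TD), false positive and false negative. Emits per-feature
#' quartile summaries per group and a Welch two-sample test comparing the
#' TP and TN groups per feature (skipped with a flag when either group is
#' empty).
#'
#' @param preds,labels pooled predictions and true labels (each sample
#'   predicted exactly once).
#' @param feature_values samples x features numeric matrix.
#' @return list with `group` (per-sample TP/TN/FP/FN), `sizes`, `summary`
#'   (long data.frame of quartiles) and `tp_vs_tn` (per-feature p-values,
#'   NA + flag when untestable).
#' @export
groupBoxplotData <- function(preds, labels, feature_values) {
  preds <- as.character(preds); labels <- as.character(labels)
  X <- as.matrix(feature_values)
  stopifnot2(length(preds) == nrow(X) && length(labels) == nrow(X),
             "predictions, labels and features must align")
  group <- ifelse(labels == "autism",
                  ifelse(preds == "autism", "TP", "FN"),
                  ifelse(preds == "autism", "FP", "TN"))
  sizes <- table(factor(group, levels = c("TP", "TN", "FP", "FN")))
  fid <- colnames(X) %||% sprintf("f%d", seq_len(ncol(X)))
  summ <- do.call(rbind, lapply(c("TP", "TN", "FP", "FN"), function(g) {
    rows <- group == g
    if (!any(rows))
      return(data.frame(group = g, feature_id = fid, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, n = 0L))
    q <- apply(X[rows, , drop = FALSE], 2L, stats::quantile,
               probs = c(0.25, 0.5, 0.75))
    data.frame(group = g, feature_id = fid, q1 = q[1L, ], median = q[2L, ],
               q3 = q[3L, ], n = sum(rows))
  }))
  testable <- sizes[["TP"]] >= 2L && sizes[["TN"]] >= 2L
  pvals <- rep(NA_real_, ncol(X))
  if (testable)
    pvals <- vapply(seq_len(ncol(X)), function(j)
      stats::t.test(X[group == "TP", j], X[group == "TN", j])$p.value,
      numeric(1L))
  list(group = group, sizes = sizes, summary = summ,
       tp_vs_tn = stats::setNames(pvals, fid), tested = testable)
}
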