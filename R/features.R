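#' Pearson functional connectivity from an ROI x time series
#'
#' @param timeseries ROI x T numeric matrix (T >= 3). Row names, if
#'   present, become the atlas labels.
#' @return symmetric unit-diagonal correlation matrix with entries in
#'   \[-1, 1\].
#' @export
pearsonFC <- function(timeseries) {
  stopifnot2(is.matrix(timeseries) && ncol(timeseries) >= 3,
             "timeseries must be an ROI x T matrix with T >= 3")
  v <- apply(timeseries, 1L, stats::var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    nm <- rownames(timeseries)[bad] %||% paste0("ROI", bad)
    stop("constant (zero-variance) ROI: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  m <- stats::cor(t(timeseries))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Upper-triangle edge indices in fixed row-major order
#'
#' Order is (1,2), (1,3), ..., (1,n), (2,3), ...: all pairs i < j sorted by
#' i then j. Every edge-vector operation in the package uses this order.
#' @param n number of regions.
#' @return data.frame with columns `i`, `j`, `id`.
#' @export
edgeIndex <- function(n) {
  stopifnot2(n >= 2, "n must be >= 2")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  data.frame(i = i, j = j, id = sprintf("e%d_%d", i, j),
             stringsAsFactors = FALSE)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' @param fc symmetric square matrix (asymmetry beyond 1e-8 is an error).
#' @return list with `values` (length n(n-1)/2, [edgeIndex()] order) and
#'   `edges` (the edge index table).
#' @export
vectorizeUpper <- function(fc) {
  stopifnot2(is.matrix(fc) && nrow(fc) == ncol(fc), "fc must be square")
  if (max(abs(fc - t(fc))) > 1e-8)
    stop("connectivity matrix is asymmetric beyond tolerance 1e-8",
         call. = FALSE)
  n <- nrow(fc)
  ei <- edgeIndex(n)
  vals <- t(fc)[lower.tri(fc)]  # row-major upper triangle
  names(vals) <- ei$id
  list(values = vals, edges = ei)
}

#' Rebuild a symmetric unit-diagonal matrix from an edge vector
#'
#' Inverse of [vectorizeUpper()] on the upper triangle.
#' @param values edge vector in [edgeIndex()] order.
#' @param n number of regions.
#' @param diag diagonal value (default 1).
#' @export
matrixFromEdges <- function(values, n, diag = 1) {
  ei <- edgeIndex(n)
  stopifnot2(length(values) == nrow(ei), "length(values) must be n(n-1)/2")
  m <- matrix(0, n, n)
  m[cbind(ei$j, ei$i)] <- values
  m <- m + t(m)
  base::diag(m) <- diag
  m
}

#' Assemble the flattened structural feature vector
#'
#' Concatenates a cortical regions x 9 measures table and a noncortical
#' regions x 7 measures table into one 1-D vector with stable
#' `region.measure` ids. The output order is fixed by the region labels
#' (cortical block first, regions sorted alphabetically, measures in
#' canonical order), so shuffled input rows produce an identical vector.
#'
#' @param cortical data.frame/matrix with region row names and the 9
#'   cortical measures as columns.
#' @param noncortical data.frame/matrix with region row names and the 7
#'   noncortical measures as columns.
#' @return named numeric vector of length `9 * nrow(cortical) +
#'   7 * nrow(noncortical)`.
#' @export
assembleStructural <- function(cortical, noncortical) {
  blk <- function(tab, nmeas, what) {
    if (is.null(tab) || nrow(tab) == 0L) return(numeric(0))
    m <- as.matrix(tab)
    stopifnot2(ncol(m) == nmeas,
               sprintf("%s table must have %d measure columns", what, nmeas))
    if (anyNA(m)) {
      bad <- rownames(m)[apply(is.na(m), 1L, any)]
      stop("missing cells for ", what, " region(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (is.null(rownames(m)))
      stop(what, " table must have region row names", call. = FALSE)
    m <- m[order(rownames(m)), , drop = FALSE]
    v <- as.vector(t(m))
    names(v) <- as.vector(t(outer(rownames(m), colnames(m), paste, sep = ".")))
    v
  }
  c(blk(cortical, 9L, "cortical"), blk(noncortical, 7L, "noncortical"))
}

#' Train-only feature standardization
#'
#' `fitStandardizer()` estimates per-feature location and scale on training
#' rows only (population, 1/n, variance convention); `applyStandardizer()`
#' transforms any rows with the training parameters. Degenerate
#' (zero-variance) columns have their scale floored at 1e-12, so constant
#' training columns standardize to exactly zero.
#'
#' @param X_train training rows x features matrix.
#' @return a `Standardizer` list with `center`, `scale` and a `floored`
#'   flag per feature.
#' @export
fitStandardizer <- function(X_train) {
  stopifnot2(is.matrix(X_train) || is.data.frame(X_train),
             "X_train must be a matrix")
  X_train <- as.matrix(X_train)
  ctr <- colMeans(X_train)
  v <- colMeans(X_train^2) - ctr^2
  sc <- sqrt(pmax(v, 0))
  floored <- sc < 1e-12
  sc[floored] <- 1e-12
  structure(list(center = ctr, scale = sc, floored = floored),
            class = "Standardizer")
}

#' @rdname fitStandardizer
#' @param s a `Standardizer`.
#' @param X rows to transform (training or held-out).
#' @export
applyStandardizer <- function(s, X) {
  stopifnot2(inherits(s, "Standardizer"), "s must be a Standardizer")
  X <- as.matrix(X)
  stopifnot2(ncol(X) == length(s$center), "feature count mismatch")
  Xc <- sweep(X, 2L, s$center, "-")
  out <- sweep(Xc, 2L, s$scale, "/")
  if (any(s$floored)) out[, s$floored] <- 0
  out
}

# Closed-form ridge fit on +/-1 labels with an unpenalized intercept.
# Dual form (via the Gram matrix) because features typically outnumber
# samples here; `gram` allows reuse across RFE iterations.
ridgeWeights <- function(X, y01, lambda = 1, gram = NULL) {
  y <- ifelse(y01 > 0, 1, -1)
  yc <- y - mean(y)
  if (is.null(gram)) gram <- tcrossprod(X)
  alpha <- solve(gram + lambda * diag(nrow(X)), yc)
  drop(crossprod(X, alpha))
}

#' Recursive feature elimination under a ridge classifier
#'
#' Iteratively fits a ridge-penalized linear classifier (closed form,
#' unit penalty by default) and eliminates the `step` features with the
#' smallest absolute coefficients, re-ranking the survivors, until one
#' feature remains. The rank is the elimination order: rank 1 survives
#' longest. Expects standardized features; fit the standardizer and run the
#' ranking on training rows only.
#'
#' @param X standardized training matrix (samples x features).
#' @param y binary labels (`"autism"`/`"td"`, factor, or 0/1; autism / the
#'   second factor level is the positive class).
#' @param step features eliminated per iteration: a fraction of the
#'   surviving set if `< 1` (default 0.1), else an integer count.
#' @param lambda ridge penalty.
#' @return a `SelectionRanking` list with `rank` (a permutation of
#'   `1..ncol(X)`, named by feature) and `n_features`.
#' @export
rfeRank <- function(X, y, step = 0.1, lambda = 1) {
  X <- as.matrix(X)
  y01 <- labelTo01(y)
  p <- ncol(X)
  stopifnot2(p >= 1L, "X must have at least one feature")
  ids <- colnames(X) %||% sprintf("f%d", seq_len(p))
  rank <- integer(p); names(rank) <- ids
  surviving <- seq_len(p)
  next_worst <- p
  gram <- tcrossprod(X)
  while (length(surviving) > 1L) {
    w <- ridgeWeights(X[, surviving, drop = FALSE], y01, lambda, gram = gram)
    n_drop <- if (step < 1) max(1L, floor(step * length(surviving)))
              else as.integer(step)
    n_drop <- min(n_drop, length(surviving) - 1L)
    ord <- order(abs(w))           # smallest |coefficient| first
    drop_local <- ord[seq_len(n_drop)]
    # worst rank to the smallest coefficient within the dropped chunk
    rank[surviving[drop_local]] <- next_worst - seq_len(n_drop) + 1L
    next_worst <- next_worst - n_drop
    Xd <- X[, surviving[drop_local], drop = FALSE]
    gram <- gram - tcrossprod(Xd)
    surviving <- surviving[-drop_local]
  }
  rank[surviving] <- 1L
  structure(list(rank = rank, n_features = p), class = "SelectionRanking")
}

#' @rdname rfeRank
#' @param r a `SelectionRanking`.
#' @param k number of features to keep (the k that survive elimination
#'   longest).
#' @return logical mask over features with exactly `k` `TRUE` entries.
#' @export
selectTopK <- function(r, k) {
  stopifnot2(inherits(r, "SelectionRanking"), "r must be a SelectionRanking")
  if (k > r$n_features)
    stop("k (", k, ") exceeds the number of features (", r$n_features, ")",
         call. = FALSE)
  r$rank <= k
}

labelTo01 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    stopifnot2(all(y %in% c("autism", "td")),
               "labels must be 'autism'/'td' (or 0/1)")
    as.integer(y == "autism")
  } else {
    stopifnot2(all(y %in% c(0, 1)), "numeric labels must be 0/1")
    as.integer(y)
  }
}

#' Encode the six non-imaging measures as a numeric block
#'
#' Age, sex (M = 1, F = 0), FIQ, motion-outlier count, motion-outlier
#' percentage and anatomical quality rate, in that order. Phenotypes enter
#' the feature matrix unselected.
#' @param pheno phenotype table ([phenotypes()] of a Cohort).
#' @return samples x 6 numeric matrix.
#' @export
phenoFeatureBlock <- function(pheno) {
  m <- cbind(age = as.numeric(pheno$age),
             sex = as.numeric(pheno$sex == "M"),
             fiq = as.numeric(pheno$fiq),
             num = as.numeric(pheno$num),
             pec = as.numeric(pheno$pec),
             rat = as.numeric(pheno$rat))
  rownames(m) <- pheno$id
  m
}

#' Assemble a named feature set from modality blocks
#'
#' Concatenates the requested modality blocks in the fixed order fmri,
#' smri, pheno into a [SummarizedExperiment::SummarizedExperiment] (features
#' x samples) whose `rowData` records each feature's modality. The six
#' phenotype measures are appended unselected for the `*+p` modes.
#'
#' @param mode one of `"s"`, `"s+p"`, `"f"`, `"f+p"`, `"s+f"`, `"s+f+p"`.
#' @param fmri,smri,pheno samples x features matrices (row names = sample
#'   ids); only the blocks the mode requires need be supplied.
#' @return SummarizedExperiment with assay `features`.
#' @export
assembleFeatureSet <- function(mode, fmri = NULL, smri = NULL, pheno = NULL) {
  modes <- c("s", "s+p", "f", "f+p", "s+f", "s+f+p")
  stopifnot2(mode %in% modes,
             paste("mode must be one of:", paste(modes, collapse = ", ")))
  want <- strsplit(mode, "+", fixed = TRUE)[[1L]]
  parts <- list()
  if ("f" %in% want) {
    stopifnot2(!is.null(fmri), "mode requires the fmri block")
    parts$fmri <- as.matrix(fmri)
  }
  if ("s" %in% want) {
    stopifnot2(!is.null(smri), "mode requires the smri block")
    parts$smri <- as.matrix(smri)
  }
  if ("p" %in% want) {
    stopifnot2(!is.null(pheno), "mode requires the pheno block")
    parts$pheno <- as.matrix(pheno)
  }
  ids <- rownames(parts[[1L]])
  stopifnot2(!is.null(ids), "blocks must carry sample ids as row names")
  for (nm in names(parts))
    if (!identical(rownames(parts[[nm]]), ids))
      stop("sample rows of block '", nm, "' do not match", call. = FALSE)
  X <- do.call(cbind, unname(parts))
  modality <- rep(names(parts), vapply(parts, ncol, 1L))
  fid <- colnames(X)
  if (anyDuplicated(fid)) stop("feature ids are not unique", call. = FALSE)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    rowData = S4Vectors::DataFrame(modality = modality, row.names = fid),
    colData = S4Vectors::DataFrame(row.names = ids))
}

#' Extract the samples x features matrix from an assembled feature set
#' @param se SummarizedExperiment from [assembleFeatureSet()].
#' @export
featureValues <- function(se) t(SummarizedExperiment::assay(se, "features"))

#' Per-feature modality of an assembled feature set
#' @param se SummarizedExperiment from [assembleFeatureSet()].
#' @export
featureModality <- function(se) {
  as.character(SummarizedExperiment::rowData(se)$modality)
}
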