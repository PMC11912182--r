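#' Train the kernel SVM baseline
#'
#' Gaussian (RBF) kernel with the "scale" bandwidth convention
#' (`gamma = 1 / (p * var(X))`); the regularization parameter C is chosen
#' from `spec$C_grid` by validation accuracy. Class scores are a logistic
#' squashing of the signed decision values, calibrated on the training
#' split.
#'
#' @param X,y standardized training features and binary labels.
#' @param X_val,y_val validation split used to select C.
#' @param spec a [modelSpec()] for `"svm"`.
#' @return a [TrainedClassifier-class] (`SVMClassifier`).
#' @export
trainSVM <- function(X, y, X_val, y_val, spec = NULL) {
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  spec <- spec %||% modelSpec("svm", ncol(X))
  y01 <- labelTo01(y); yv <- labelTo01(y_val)
  if (length(unique(y01)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  gamma <- 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
  yf <- factor(ifelse(y01 == 1L, "autism", "td"), levels = c("td", "autism"))
  best <- NULL
  for (C in spec$C_grid) {
    fit <- e1071::svm(x = X, y = yf, kernel = "radial", gamma = gamma,
                      cost = C, scale = FALSE)
    acc <- mean((as.character(predict(fit, X_val)) == "autism") == (yv == 1L))
    if (is.null(best) || acc > best$acc) best <- list(fit = fit, C = C, acc = acc)
  }
  dv <- decisionValues(best$fit, X)
  calib <- fitLogisticCalibration(dv, y01)
  methods::new("SVMClassifier", architecture = "svm",
               featureIds = colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
               featureRange = featureRangeOf(X), seed = spec$seed,
               fit = best$fit, calib = calib, cost = best$C)
}

decisionValues <- function(fit, X) {
  pr <- predict(fit, as.matrix(X), decision.values = TRUE)
  drop(attr(pr, "decision.values"))
}

# Monotone logistic map from decision values to autism probability; the
# slope sign absorbs the decision-value orientation of the fit.
fitLogisticCalibration <- function(dv, y01) {
  co <- tryCatch(
    suppressWarnings(stats::coef(stats::glm(y01 ~ dv,
                                            family = stats::binomial()))),
    error = function(e) NULL)
  if (is.null(co) || anyNA(co) || !all(is.finite(co))) {
    # perfectly separated or degenerate: fall back to a fixed-slope squash
    s <- if (stats::cor(dv, y01) >= 0) 1 else -1
    co <- c(0, 4 * s / max(stats::sd(dv), 1e-8))
  }
  # cap the slope so perfect separation does not produce hard 0/1 scores
  co[2L] <- sign(co[2L]) * min(abs(co[2L]), 50 / max(stats::sd(dv), 1e-8))
  unname(co)
}

#' @rdname classScores
#' @export
setMethod("classScores", "SVMClassifier", function(object, newdata = NULL, ...) {
  dv <- decisionValues(object@fit, newdata)
  p <- sigmoid(object@calib[1L] + object@calib[2L] * dv)
  cbind(td = 1 - p, autism = p)
})

#' @rdname inputGradient
#' @export
setMethod("inputGradient", "SVMClassifier", function(object, x,
                                                     class = "autism", ...) {
  stop("input gradients are not supported for the svm architecture; ",
       "saliency analysis excludes it", call. = FALSE)
})
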