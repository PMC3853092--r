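# Multi-class dose classification: stratified splitting, 10-fold CV of a
# radial-basis SVM (one-vs-one, libsvm), exhaustive parameter grid
# search, and independent-test evaluation with a confusion matrix.
# Feature standardization is always fit on the training side only.

#' The 16-value SVM parameter grid
#'
#' Both the cost C and the kernel width gamma are tuned over
#' `{2^-7, 2^-6, ..., 2^7, 2^8}`.
#'
#' @return numeric(16).
#' @export
svmParamGrid <- function() 2^seq(-7, 8)

#' Stratified train/test split
#'
#' Per class, `round(fraction x n)` rows (round-half-up) go to the
#' training set, the remainder to the test set; deterministic for a
#' fixed seed.
#'
#' @param table a [FeatureTable-class].
#' @param trainFraction fraction per class assigned to training.
#' @param seed RNG seed.
#' @return list of two `FeatureTable`s: `train`, `test`.
#' @export
stratifiedSplit <- function(table, trainFraction = 2 / 3, seed = 1L) {
  dose <- doseLabels(table)
  if (any(table(dose) < 2L))
    stop("every class needs at least 2 rows to split")
  withSeed(seed, {
    trainIdx <- unlist(lapply(sort(unique(dose)), function(d) {
      rows <- which(dose == d)
      nTrain <- floor(trainFraction * length(rows) + 0.5)  # round half up
      sample(rows, nTrain)
    }))
  })
  trainIdx <- sort(trainIdx)
  list(train = table[, trainIdx], test = table[, -trainIdx])
}

# z-score standardization fit on `ref`, applied to `x`; constant columns
# pass through unscaled.
standardizeBy <- function(x, ref) {
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  sweep(sweep(x, 2, mu), 2, sdv, "/")
}

# Stratified fold assignment: integer vector of fold ids.
stratifiedFolds <- function(classes, folds, seed) {
  withSeed(seed, {
    ids <- integer(length(classes))
    for (cl in unique(classes)) {
      rows <- sample(which(classes == cl))
      ids[rows] <- rep_len(seq_len(folds), length(rows))
    }
    ids
  })
}

#' Cross-validated SVM accuracy
#'
#' Mean accuracy (percent correct over all held-out rows) of a
#' radial-basis soft-margin SVM over stratified folds; one-vs-one
#' multi-class, standardization fit within each training fold.
#'
#' @param table a [FeatureTable-class]; doses are the class labels.
#' @param C,gamma SVM parameters.
#' @param folds number of folds.
#' @param seed fold-assignment seed.
#' @param features optional character/integer subset of feature columns.
#' @return accuracy in percent.
#' @export
cvAccuracy <- function(table, C = 1, gamma = 1 / 13, folds = 10,
                       seed = 1L, features = NULL) {
  mat <- featureMatrix(table)
  if (!is.null(features)) mat <- mat[, features, drop = FALSE]
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  cls <- factor(doseLabels(table)[keep])
  if (nlevels(droplevels(cls)) < 2L)
    stop("cross-validation needs at least two classes")
  ids <- stratifiedFolds(as.integer(cls), folds, seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- ids != f; te <- ids == f
    if (!any(te)) next
    xtr <- standardizeBy(mat[tr, , drop = FALSE], mat[tr, , drop = FALSE])
    xte <- standardizeBy(mat[te, , drop = FALSE], mat[tr, , drop = FALSE])
    fit <- e1071::svm(xtr, cls[tr], kernel = "radial", cost = C,
                      gamma = gamma, scale = FALSE)
    correct <- correct + sum(predict(fit, xte) == cls[te])
  }
  100 * correct / length(cls)
}

#' Exhaustive SVM parameter grid search
#'
#' Sweeps the full 16 x 16 (C, gamma) grid maximizing cross-validated
#' accuracy; ties break toward smaller C, then smaller gamma.
#'
#' @param table a [FeatureTable-class].
#' @param folds CV folds.
#' @param seed fold seed (fixed across grid points).
#' @param features optional feature subset.
#' @param grid parameter values swept for both C and gamma.
#' @return list: `C`, `gamma`, `cvAccuracy`.
#' @export
gridSearchSVM <- function(table, folds = 10, seed = 1L, features = NULL,
                          grid = svmParamGrid()) {
  best <- list(C = NA, gamma = NA, cvAccuracy = -Inf)
  for (C in grid) for (g in grid) {   # ascending: first hit wins ties
    acc <- cvAccuracy(table, C, g, folds, seed, features)
    if (acc > best$cvAccuracy)
      best <- list(C = C, gamma = g, cvAccuracy = acc)
  }
  best
}

#' Independent-test evaluation
#'
#' Fits the SVM on the full training table and tabulates per-class
#' predictions on the disjoint test table.
#'
#' @param train,test [FeatureTable-class] objects with identical feature
#'   sets.
#' @param C,gamma SVM parameters.
#' @param features optional feature subset.
#' @return list: `accuracy` (percent), `confusion` (k x k matrix, rows =
#'   true class).
#' @export
evaluateIndependent <- function(train, test, C = 1, gamma = 1 / 13,
                                features = NULL) {
  xtr <- featureMatrix(train); xte <- featureMatrix(test)
  if (!identical(colnames(xtr), colnames(xte)))
    stop("train and test feature sets differ")
  if (!is.null(features)) {
    xtr <- xtr[, features, drop = FALSE]
    xte <- xte[, features, drop = FALSE]
  }
  ktr <- stats::complete.cases(xtr); kte <- stats::complete.cases(xte)
  xtr <- xtr[ktr, , drop = FALSE]; xte <- xte[kte, , drop = FALSE]
  lv <- as.character(sort(unique(c(doseLabels(train), doseLabels(test)))))
  ytr <- factor(doseLabels(train)[ktr], levels = lv)
  yte <- factor(doseLabels(test)[kte], levels = lv)
  fit <- e1071::svm(standardizeBy(xtr, xtr), ytr, kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  pred <- predict(fit, standardizeBy(xte, xtr))
  confusion <- table(true = yte, predicted = pred)
  list(accuracy = 100 * sum(diag(confusion)) / sum(confusion),
       confusion = unclass(confusion))
}

#' Fraction of misclassifications on adjacent classes
#'
#' For ordinal dose classes, the share of off-diagonal confusion-matrix
#' mass sitting immediately next to the diagonal.
#'
#' @param confusion square counts matrix with ordered classes.
#' @return fraction in `[0, 1]`; NA when there are no errors.
#' @export
adjacentErrorFraction <- function(confusion) {
  k <- nrow(confusion)
  off <- confusion; diag(off) <- 0
  total <- sum(off)
  if (total == 0) return(NA_real_)
  adj <- sum(off[cbind(seq_len(k - 1), seq_len(k - 1) + 1)]) +
    sum(off[cbind(seq_len(k - 1) + 1, seq_len(k - 1))])
  adj / total
}
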