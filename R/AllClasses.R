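#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats lm coef fitted predict sd var median quantile rnorm runif
#'   rpois bartlett.test oneway.test shapiro.test ptukey qtukey cor pf
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Geometric specification of one soma
#'
#' A soma is rendered as a filled bright disk. Coordinates are in pixels,
#' `(row, col)`, 1-based.
#'
#' @slot center numeric(2), disk center `(row, col)`.
#' @slot radius disk radius in pixels (>= 3).
#' @slot peakIntensity gray level of the rendered disk (16-bit scale).
#' @export
setClass("SomaSpec", representation(
  center = "numeric", radius = "numeric", peakIntensity = "numeric"
))

setValidity("SomaSpec", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (object@radius < 3) return("radius must be >= 3 px")
  if (object@peakIntensity <= 0) return("peakIntensity must be positive")
  TRUE
})

#' Construct a SomaSpec
#'
#' @param center numeric(2) `(row, col)` disk center, pixels.
#' @param radius disk radius in pixels, at least 3.
#' @param peakIntensity rendered gray level.
#' @return A [SomaSpec-class] object.
#' @export
somaSpec <- function(center, radius, peakIntensity = 600) {
  new("SomaSpec", center = as.numeric(center), radius = as.numeric(radius),
      peakIntensity = as.numeric(peakIntensity))
}

#' Geometric specification of one neurite
#'
#' A neurite is a polyline stroke attached to a soma, optionally carrying
#' sub-branches that attach on the parent path. The path must start within
#' 1 px of the perimeter of its soma.
#'
#' @slot attachmentSoma integer index into the scene's soma list.
#' @slot path n x 2 matrix of `(row, col)` vertices, starting at the soma
#'   perimeter.
#' @slot branches list; each element is `list(at = <vertex index on parent
#'   path>, path = <m x 2 matrix>)` whose path starts at the parent vertex.
#' @slot width stroke width in pixels (>= 1).
#' @slot intensity rendered gray level, below the soma peak.
#' @export
setClass("NeuriteSpec", representation(
  attachmentSoma = "integer", path = "matrix", branches = "list",
  width = "numeric", intensity = "numeric"
))

setValidity("NeuriteSpec", function(object) {
  if (ncol(object@path) != 2L || nrow(object@path) < 2L)
    return("path must be an n x 2 matrix with n >= 2")
  if (object@width < 1) return("width must be >= 1 px")
  for (b in object@branches) {
    if (!is.list(b) || is.null(b$at) || is.null(b$path))
      return("each branch needs fields 'at' and 'path'")
    if (b$at < 1L || b$at > nrow(object@path))
      return("branch attachment index outside parent path")
    if (max(abs(b$path[1, ] - object@path[b$at, ])) > 1)
      return("branch path must start at its parent vertex")
  }
  TRUE
})

#' Construct a NeuriteSpec
#'
#' @param attachmentSoma index of the soma the neurite attaches to.
#' @param path n x 2 matrix of polyline vertices `(row, col)`.
#' @param branches list of `list(at=, path=)` sub-branches.
#' @param width stroke width, pixels.
#' @param intensity rendered gray level.
#' @return A [NeuriteSpec-class] object.
#' @export
neuriteSpec <- function(attachmentSoma, path, branches = list(),
                        width = 3, intensity = 300) {
  new("NeuriteSpec", attachmentSoma = as.integer(attachmentSoma),
      path = path, branches = branches, width = as.numeric(width),
      intensity = as.numeric(intensity))
}

#' Exact ground truth of a synthetic scene
#'
#' Computed from the geometric specifications, never from the rendered
#' pixels, so it can serve as an oracle for feature extraction.
#'
#' @slot somaCount number of somata placed.
#' @slot somaAreaPx pixels covered by the union of all soma disks.
#' @slot neuriteLengthPx total Euclidean arc length of all polylines.
#' @slot neuriteAreaPx pixels covered by neurite strokes (outside somata).
#' @slot nAttachment number of neurite-soma attachment points.
#' @slot nEnding number of free polyline termini.
#' @slot nBranch number of sub-branch junctions.
#' @export
setClass("SceneGroundTruth", representation(
  somaCount = "integer", somaAreaPx = "integer", neuriteLengthPx = "numeric",
  neuriteAreaPx = "integer", nAttachment = "integer", nEnding = "integer",
  nBranch = "integer"
))

setValidity("SceneGroundTruth", function(object) {
  counts <- c(object@somaCount, object@somaAreaPx, object@neuriteLengthPx,
              object@neuriteAreaPx, object@nAttachment, object@nEnding,
              object@nBranch)
  if (any(counts < 0)) return("all ground-truth quantities must be >= 0")
  TRUE
})

setMethod("show", "SceneGroundTruth", function(object) {
  cat("SceneGroundTruth:", object@somaCount, "somata,",
      sprintf("%.1f", object@neuriteLengthPx), "px neurite length,",
      object@nAttachment, "attach /", object@nEnding, "end /",
      object@nBranch, "branch points\n")
})

#' Soma/neurite segmentation of one image
#'
#' Holds the binary soma and neurite masks, the one-pixel-wide neurite
#' skeleton and the three landmark point sets. Point sets are n x 2
#' matrices of `(row, col)` coordinates.
#'
#' @slot somaMask logical matrix.
#' @slot neuriteMask logical matrix, disjoint from `somaMask`.
#' @slot skeleton logical matrix, at most 1 px wide.
#' @slot attachmentPoints,endingPoints,branchPoints n x 2 coordinate
#'   matrices.
#' @export
setClass("SegmentationResult", representation(
  somaMask = "matrix", neuriteMask = "matrix", skeleton = "matrix",
  attachmentPoints = "matrix", endingPoints = "matrix",
  branchPoints = "matrix"
))

setValidity("SegmentationResult", function(object) {
  d <- dim(object@somaMask)
  if (!identical(d, dim(object@neuriteMask)) ||
      !identical(d, dim(object@skeleton)))
    return("masks and skeleton must share dimensions")
  if (any(object@somaMask & object@neuriteMask))
    return("soma and neurite masks must be disjoint")
  if (any(object@skeleton & !object@neuriteMask))
    return("skeleton must lie inside the neurite mask")
  TRUE
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult", paste(dim(object@somaMask), collapse = " x "),
      "px:", sum(object@somaMask), "soma px,", sum(object@neuriteMask),
      "neurite px,", sum(object@skeleton), "skeleton px;",
      nrow(object@attachmentPoints), "attach /",
      nrow(object@endingPoints), "end /",
      nrow(object@branchPoints), "branch points\n")
})

#' @rdname SegmentationResult-class
#' @param object a `SegmentationResult`.
#' @export
setGeneric("somaMask", function(object) standardGeneric("somaMask"))
#' @rdname SegmentationResult-class
#' @export
setGeneric("neuriteMask", function(object) standardGeneric("neuriteMask"))
#' @rdname SegmentationResult-class
#' @export
setGeneric("skeletonMask", function(object) standardGeneric("skeletonMask"))

#' @rdname SegmentationResult-class
setMethod("somaMask", "SegmentationResult", function(object) object@somaMask)
#' @rdname SegmentationResult-class
setMethod("neuriteMask", "SegmentationResult",
          function(object) object@neuriteMask)
#' @rdname SegmentationResult-class
setMethod("skeletonMask", "SegmentationResult",
          function(object) object@skeleton)

#' Feature table for a set of images
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] with
#' features in rows, images in columns, and a mandatory `dose_ng_per_ml`
#' column in `colData`. This is the exchange object between feature
#' extraction, dose-response statistics, and classification.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"dose_ng_per_ml" %in%
      colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'dose_ng_per_ml' column")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values images x features numeric matrix (rows are images) or
#'   features x images matrix with `byImage = FALSE`.
#' @param dose numeric vector of dose labels (ng/mL), one per image.
#' @param imageIds optional image identifiers.
#' @param byImage if `TRUE` (default), `values` rows are images.
#' @return A [FeatureTable-class] object.
#' @examples
#' ft <- featureTable(matrix(rnorm(20), 10, 2,
#'   dimnames = list(NULL, c("f1", "f2"))), dose = rep(c(0, 10), each = 5))
#' doseLabels(ft)
#' @export
featureTable <- function(values, dose, imageIds = NULL, byImage = TRUE) {
  m <- as.matrix(values)
  if (byImage) m <- t(m)
  if (is.null(colnames(m)))
    colnames(m) <- if (!is.null(imageIds)) imageIds else
      sprintf("img%03d", seq_len(ncol(m)))
  if (length(dose) != ncol(m))
    stop("length(dose) must equal the number of images")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    colData = S4Vectors::DataFrame(dose_ng_per_ml = as.numeric(dose),
                                   row.names = colnames(m)))
  new("FeatureTable", se)
}

#' @rdname FeatureTable-class
#' @param object a `FeatureTable`.
#' @export
setGeneric("doseLabels", function(object) standardGeneric("doseLabels"))
#' @rdname FeatureTable-class
setMethod("doseLabels", "FeatureTable", function(object)
  SummarizedExperiment::colData(object)$dose_ng_per_ml)

#' @rdname FeatureTable-class
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname FeatureTable-class
#' @return `featureMatrix` returns an images x features matrix.
setMethod("featureMatrix", "FeatureTable", function(object)
  t(SummarizedExperiment::assay(object, "features")))

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", ncol(object), "images x", nrow(object), "features;",
      "doses:", paste(sort(unique(doseLabels(object))), collapse = ", "),
      "ng/mL\n")
})

#' Log-dose regression result for one feature
#'
#' Linear and quadratic ordinary least squares fits of a feature on
#' x = log10(dose), the 0-dose control mapped to x = 0, together with the
#' 5-percent-improvement model choice, the fraction of between-group
#' variation captured by the selected model, and the >90 percent success
#' flag.
#'
#' @slot feature feature name.
#' @slot linear named numeric: `intercept`, `slope`, `r2` (percent, on the
#'   total-variance scale when available).
#' @slot quadratic named numeric: `a` (x^2), `b` (x), `c`, `r2`.
#' @slot selectedModel `"linear"` or `"quadratic"`.
#' @slot varianceExplained percent of between-group variation captured by
#'   the selected model (capped at 100 for reporting).
#' @slot successful `TRUE` when `varianceExplained > 90`.
#' @slot equation human-readable equation of the selected model.
#' @export
setClass("DoseRegressionResult", representation(
  feature = "character", linear = "numeric", quadratic = "numeric",
  selectedModel = "character", varianceExplained = "numeric",
  successful = "logical", equation = "character"
))

setValidity("DoseRegressionResult", function(object) {
  if (!object@selectedModel %in% c("linear", "quadratic"))
    return("selectedModel must be 'linear' or 'quadratic'")
  TRUE
})

setMethod("show", "DoseRegressionResult", function(object) {
  cat(sprintf(
    "DoseRegressionResult [%s]: %s model, VE = %.1f%%%s\n  %s\n",
    object@feature, object@selectedModel, object@varianceExplained,
    if (isTRUE(object@successful)) " (successful)" else "",
    object@equation))
})

#' @rdname DoseRegressionResult-class
#' @param object a `DoseRegressionResult`.
#' @export
setGeneric("selectedModel", function(object) standardGeneric("selectedModel"))
#' @rdname DoseRegressionResult-class
setMethod("selectedModel", "DoseRegressionResult",
          function(object) object@selectedModel)

#' @rdname DoseRegressionResult-class
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))
#' @rdname DoseRegressionResult-class
setMethod("varianceExplained", "DoseRegressionResult",
          function(object) object@varianceExplained)

#' Aggregated feature-selection report
#'
#' Selection frequencies of each feature over repeated genetic-algorithm
#' runs, plus the single best solution by cross-validation accuracy.
#'
#' @slot counts named integer vector, times each feature entered a run's
#'   final solution.
#' @slot nRuns number of runs aggregated.
#' @slot best list: `features`, `C`, `gamma`, `cvAccuracy`.
#' @slot runs list of per-run final solutions.
#' @export
setClass("SelectionReport", representation(
  counts = "integer", nRuns = "integer", best = "list", runs = "list"
))

setValidity("SelectionReport", function(object) {
  if (any(object@counts < 0L) || any(object@counts > object@nRuns))
    return("counts must lie in [0, nRuns]")
  TRUE
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport over", object@nRuns, "runs\n")
  top <- sort(object@counts, decreasing = TRUE)
  cat("  top features:",
      paste(sprintf("%s (%d)", names(top)[seq_len(min(5, length(top)))],
                    top[seq_len(min(5, length(top)))]), collapse = ", "),
      "\n")
  cat(sprintf("  best: {%s}, C = %g, gamma = %g, 10-CV = %.2f%%\n",
              paste(object@best$features, collapse = ", "),
              object@best$C, object@best$gamma, object@best$cvAccuracy))
})

#' @rdname SelectionReport-class
#' @param object a `SelectionReport`.
#' @export
setGeneric("selectionCounts",
           function(object) standardGeneric("selectionCounts"))
#' @rdname SelectionReport-class
setMethod("selectionCounts", "SelectionReport", function(object)
  object@counts)
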