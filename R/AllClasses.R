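#' HOG descriptor geometry
#'
#' Holds the Histogram-of-Oriented-Gradients geometry: square cells of
#' `cellSide` pixels, square blocks of `blockSide` cells slid with a
#' `blockStride`-cell step, and `nBins` orientation bins.  With the
#' defaults (8-pixel cells, 2x2-cell blocks, stride 1, 9 unsigned bins)
#' a 255x255 image yields a 32,400-element descriptor: 31x31 cells give
#' 30x30 blocks of 2*2*9 = 36 entries each.
#'
#' @slot cellSide integer, pixels per cell side.
#' @slot blockSide integer, cells per block side.
#' @slot blockStride integer, block step in cells.
#' @slot nBins integer, orientation bins over [0, 180) degrees
#'   (unsigned gradients) or [0, 360) when `signedGradients` is TRUE.
#' @slot signedGradients logical, keep gradient sign (default FALSE).
#' @slot blockNorm character, block normalisation; only `"L2-Hys"`
#'   (L2 normalise, clip at `hysClip`, renormalise) is implemented.
#' @slot hysClip numeric, clipping level for L2-Hys (default 0.2).
#'
#' @seealso [HOGParams()], [hogDescriptor()], [hogLength()]
#' @export
setClass("HOGParams",
  representation(
    cellSide = "integer", blockSide = "integer", blockStride = "integer",
    nBins = "integer", signedGradients = "logical",
    blockNorm = "character", hysClip = "numeric"),
  prototype(
    cellSide = 8L, blockSide = 2L, blockStride = 1L, nBins = 9L,
    signedGradients = FALSE, blockNorm = "L2-Hys", hysClip = 0.2))

setValidity("HOGParams", function(object) {
  msg <- character()
  for (s in c("cellSide", "blockSide", "blockStride", "nBins"))
    if (length(slot(object, s)) != 1L || slot(object, s) < 1L)
      msg <- c(msg, sprintf("'%s' must be a positive integer", s))
  if (!identical(object@blockNorm, "L2-Hys"))
    msg <- c(msg, "only 'L2-Hys' block normalisation is implemented")
  if (object@hysClip <= 0)
    msg <- c(msg, "'hysClip' must be positive")
  if (length(msg)) msg else TRUE
})

#' Principal-component model of a feature matrix
#'
#' Mean-centred PCA fitted by eigendecomposition of the sample Gram
#' matrix (the economical side when features far outnumber samples, as
#' for 32,400-dimensional HOG descriptors).  At most `nSamples - 1`
#' components carry positive variance.
#'
#' @slot mean numeric, per-feature mean (length = number of features).
#' @slot components numeric matrix, k x nFeatures orthonormal rows
#'   ordered by decreasing variance; sign fixed so each row's
#'   largest-magnitude loading is positive.
#' @slot explainedVariance numeric, non-increasing, length k.
#' @slot nSamples integer, rows used in the fit.
#'
#' @seealso [fitPCA()], [pcaTransform()]
#' @export
setClass("PCAModel",
  representation(mean = "numeric", components = "matrix",
                 explainedVariance = "numeric", nSamples = "integer"))

setValidity("PCAModel", function(object) {
  msg <- character()
  k <- nrow(object@components)
  if (length(object@explainedVariance) != k)
    msg <- c(msg, "one variance per component is required")
  if (k > 1 && any(diff(object@explainedVariance) > 1e-8))
    msg <- c(msg, "explained variances must be non-increasing")
  if (any(object@explainedVariance < -1e-8))
    msg <- c(msg, "explained variances must be non-negative")
  if (ncol(object@components) != length(object@mean))
    msg <- c(msg, "components and mean disagree on feature count")
  if (length(msg)) msg else TRUE
})

#' Extreme Learning Machine model
#'
#' Single-hidden-layer feed-forward network: random (or optimizer-tuned)
#' input weights `w` (L x n, in [-1,1]) and hidden biases `b` (length L,
#' in [0,1]), sigmoid activation, and output weights `rho` (L x m)
#' solved in closed form as rho = pinv(H) T, the minimum-norm
#' least-squares solution for one-hot targets T.
#'
#' @slot w numeric matrix, L x n input weights.
#' @slot b numeric, hidden biases, length L.
#' @slot rho numeric matrix, L x m output weights.
#' @slot activation character, activation tag ("sigmoid").
#' @slot nClasses integer, number of classes m.
#'
#' @seealso [trainELM()], [trainGWOELM()], [predict,ELMModel-method]
#' @export
setClass("ELMModel",
  representation(w = "matrix", b = "numeric", rho = "matrix",
                 activation = "character", nClasses = "integer"))

setValidity("ELMModel", function(object) {
  msg <- character()
  L <- nrow(object@w)
  if (length(object@b) != L)
    msg <- c(msg, "one bias per hidden node is required")
  if (nrow(object@rho) != L)
    msg <- c(msg, "'rho' must have one row per hidden node")
  if (object@nClasses < 2L)
    msg <- c(msg, "at least two classes are required")
  if (ncol(object@rho) != object@nClasses)
    msg <- c(msg, "'rho' must have one column per class")
  if (!all(is.finite(object@rho)))
    msg <- c(msg, "'rho' must be finite")
  if (!identical(object@activation, "sigmoid"))
    msg <- c(msg, "only the sigmoid activation is implemented")
  if (length(msg)) msg else TRUE
})

#' Result of a Gray Wolf Optimization run
#'
#' @slot bestPosition numeric, the alpha wolf's position after the last
#'   iteration.
#' @slot bestFitness numeric, its fitness.
#' @slot trace numeric, alpha fitness after initialisation (element 1)
#'   and after each iteration; monotone non-decreasing when maximising.
#' @slot nAgents integer, population size.
#' @slot itMax integer, iteration budget.
#' @slot maximize logical, optimisation sense.
#'
#' @seealso [gwoOptimize()]
#' @export
setClass("GWOFit",
  representation(bestPosition = "numeric", bestFitness = "numeric",
                 trace = "numeric", nAgents = "integer", itMax = "integer",
                 maximize = "logical"))

#' Classification evaluation report
#'
#' Confusion counts and the seven derived measures: accuracy, precision,
#' recall, specificity, Matthews correlation coefficient, F-measure and
#' G-mean (the geometric mean of recall and precision).  For multi-class
#' problems the counts are one-vs-rest micro-aggregates and accuracy is
#' the class-averaged one-vs-rest accuracy.  Metrics are stored as
#' fractions (MCC in [-1,1]); [metricsTable()] reports percentages.
#'
#' @slot counts numeric, named tp/fp/fn/tn totals.
#' @slot metrics numeric, named fractions.
#' @slot mode character, "binary" or "multiclass".
#' @slot nClasses integer.
#'
#' @seealso [binaryMetrics()], [multiclassMetrics()], [metricsTable()]
#' @export
setClass("EvalReport",
  representation(counts = "numeric", metrics = "numeric",
                 mode = "character", nClasses = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must contain non-negative tp/fp/fn/tn")
  if (sum(object@counts) < 1)
    msg <- c(msg, "counts must total at least one observation")
  if (!object@mode %in% c("binary", "multiclass"))
    msg <- c(msg, "mode must be 'binary' or 'multiclass'")
  if (length(msg)) msg else TRUE
})

#' Stratified train/test partition
#'
#' Index partition of a labelled dataset, stratified so each class is
#' split as close to the requested training fraction as integer counts
#' allow (floor allocation, remainder to the largest fractional parts).
#'
#' @slot trainIndices integer.
#' @slot testIndices integer.
#' @slot trainFraction numeric.
#' @slot seed integer seed the shuffle used.
#'
#' @seealso [stratifiedSplit()]
#' @export
setClass("DatasetSplit",
  representation(trainIndices = "integer", testIndices = "integer",
                 trainFraction = "numeric", seed = "integer"))

setValidity("DatasetSplit", function(object) {
  msg <- character()
  if (length(intersect(object@trainIndices, object@testIndices)))
    msg <- c(msg, "train and test indices must be disjoint")
  if (anyDuplicated(object@trainIndices) || anyDuplicated(object@testIndices))
    msg <- c(msg, "indices must be unique")
  if (length(object@testIndices) < 1L)
    msg <- c(msg, "the test set must not be empty")
  if (length(msg)) msg else TRUE
})
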