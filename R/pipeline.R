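#' Stratified train/test split
#'
#' Splits sample indices so that each class contributes
#' `floor(trainFraction * nClass)` training samples, with the overall
#' remainder (to reach `floor(trainFraction * N)` training samples in
#' total) assigned to the classes with the largest fractional parts
#' (ties to the lower class label).  A balanced 5 x 190 dataset at 0.8
#' therefore splits 152/38 in every class; class counts
#' (168, 25, 168, 93, 62) give 412 train / 104 test.  Within-class
#' assignment is a seeded shuffle, so the split is reproducible.
#'
#' @param labels integer class labels.
#' @param trainFraction fraction of each class used for training,
#'   in (0, 1) (default 0.8).
#' @param seed integer RNG seed.
#' @return a [DatasetSplit-class] object.
#' @examples
#' sp <- stratifiedSplit(rep(1:5, each = 190), seed = 1)
#' length(trainIndices(sp)); length(testIndices(sp))
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.8, seed = 1L) {
  labels <- as.integer(labels)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("'trainFraction' must lie strictly between 0 and 1 ",
         "(the test set must not be empty)")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 members to be split")
  raw <- as.numeric(counts) * trainFraction
  nTrain <- floor(raw)
  remainder <- floor(trainFraction * length(labels)) - sum(nTrain)
  if (remainder > 0) {
    extra <- order(raw - nTrain, decreasing = TRUE)[seq_len(remainder)]
    nTrain[extra] <- nTrain[extra] + 1L
  }
  classLevels <- as.integer(names(counts))
  withr::with_seed(as.integer(seed), {
    trainIdx <- unlist(lapply(seq_along(classLevels), function(ci) {
      idx <- which(labels == classLevels[ci])
      sample(idx)[seq_len(nTrain[ci])]
    }))
  })
  trainIdx <- sort(as.integer(trainIdx))
  testIdx <- setdiff(seq_along(labels), trainIdx)
  new("DatasetSplit", trainIndices = trainIdx,
      testIndices = as.integer(testIdx),
      trainFraction = trainFraction, seed = as.integer(seed))
}

#' @rdname trainIndices
#' @param object a [DatasetSplit-class] object.
#' @return integer indices of the training (resp. test) rows.
#' @export
setMethod("trainIndices", "DatasetSplit", function(object) object@trainIndices)

#' Split accessors
#' @rdname trainIndices
#' @export
setMethod("testIndices", "DatasetSplit", function(object) object@testIndices)

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d test (fraction %.2f, seed %d)\n",
              length(object@trainIndices), length(object@testIndices),
              object@trainFraction, object@seed))
})

#' Collapse severity grades to disease presence
#'
#' Grade 1 (no disease) maps to class 1 (negative); grades 2-5 (mild
#' through proliferative) map to class 2 (positive, "disease
#' present").  Class 2 is the positive class in binary evaluation.
#'
#' @param labels integer grades in 1..5.
#' @return integer labels in 1..2.
#' @examples
#' binarizeLabels(1:5)
#' @export
binarizeLabels <- function(labels) {
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > 5L))
    stop("labels must lie in 1..5")
  ifelse(labels == 1L, 1L, 2L)
}

#' Build the experiment grid
#'
#' One cell per (dataset, mode, hidden-node count) combination.  The
#' default hidden-node sweep 100, 125, ..., 300 over two modes and two
#' datasets gives 36 cells.
#'
#' @param hiddenNodes integer vector of hidden-node counts (default
#'   `seq(100, 300, by = 25)`).
#' @param modes character subset of `c("binary", "multiclass")`.
#' @param datasets character vector of dataset names.
#' @return data.frame with columns dataset, mode, L and cell (index).
#' @examples
#' nrow(buildExperimentGrid(datasets = c("a", "b")))  # 36
#' @export
buildExperimentGrid <- function(hiddenNodes = seq(100L, 300L, by = 25L),
                                modes = c("binary", "multiclass"),
                                datasets = "dataset") {
  modes <- match.arg(modes, several.ok = TRUE)
  grid <- expand.grid(L = as.integer(hiddenNodes), mode = modes,
                      dataset = datasets, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("dataset", "mode", "L")]
  grid$cell <- seq_len(nrow(grid))
  grid
}

#' Run the full experiment grid
#'
#' For every grid cell: stratify-split the named dataset 80/20,
#' binarise the labels when the mode asks for it, train a GWO-ELM on
#' the training rows (with a per-cell derived seed, `seed + cell`),
#' predict the test rows, and evaluate with the matching metric
#' scheme.  Returns one row per cell with the seven test metrics.
#'
#' @param datasets named list; each element a list with `X` (feature
#'   matrix) and `y` (integer grades 1..5).
#' @param hiddenNodes hidden-node sweep (default `seq(100, 300, 25)`).
#' @param modes modes to run (default both).
#' @param nAgents,itMax GWO settings (defaults 50 and 100).
#' @param trainFraction training fraction (default 0.8).
#' @param seed integer base seed.
#' @param classifier `"gwo-elm"` (default) or `"elm"` for the
#'   unoptimized baseline.
#' @return data.frame: one row per cell with dataset, mode, L, seed,
#'   train/test accuracy and the seven metric percentages.
#' @examples
#' d <- makeFeatureDataset(nPerClass = 12, seed = 1)
#' runExperimentGrid(list(synth = d), hiddenNodes = 20, modes = "binary",
#'                   nAgents = 4, itMax = 2, seed = 1)
#' @export
runExperimentGrid <- function(datasets, hiddenNodes = seq(100L, 300L, by = 25L),
                              modes = c("binary", "multiclass"),
                              nAgents = 50L, itMax = 100L,
                              trainFraction = 0.8, seed = 1L,
                              classifier = c("gwo-elm", "elm")) {
  classifier <- match.arg(classifier)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("'datasets' must be a named list")
  grid <- buildExperimentGrid(hiddenNodes, modes, names(datasets))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    ds <- datasets[[cell$dataset]]
    y <- if (cell$mode == "binary") binarizeLabels(ds$y) else as.integer(ds$y)
    cellSeed <- as.integer(seed) + cell$cell
    sp <- stratifiedSplit(y, trainFraction, seed = cellSeed)
    tr <- trainIndices(sp); te <- testIndices(sp)
    m <- max(y)
    if (classifier == "gwo-elm") {
      fit <- trainGWOELM(ds$X[tr, , drop = FALSE], y[tr], L = cell$L,
                         nAgents = nAgents, itMax = itMax,
                         seed = cellSeed, nClasses = m)
      model <- fit$model
    } else {
      model <- trainELM(ds$X[tr, , drop = FALSE], y[tr], L = cell$L,
                        seed = cellSeed, nClasses = m)
    }
    predTr <- predict(model, ds$X[tr, , drop = FALSE])
    predTe <- predict(model, ds$X[te, , drop = FALSE])
    rep <- evaluatePredictions(y[te], predTe,
                               mode = if (cell$mode == "binary") "binary"
                                      else "multiclass",
                               nClasses = m)
    cbind(cell, seed = cellSeed,
          trainAccuracy = mean(predTr == y[tr]),
          testAccuracy = mean(predTe == y[te]),
          metricsTable(rep))
  })
  do.call(rbind, rows)
}

#' Best grid cell per dataset and mode
#'
#' Selects, within each (dataset, mode) group, the row with the
#' highest test accuracy (ties to the smaller hidden-node count) --
#' the "highest outcomes" view of a grid run.
#'
#' @param results data.frame from [runExperimentGrid()].
#' @return data.frame with one row per (dataset, mode).
#' @examples
#' d <- makeFeatureDataset(nPerClass = 12, seed = 1)
#' r <- runExperimentGrid(list(s = d), hiddenNodes = c(10, 20),
#'                        modes = "binary", nAgents = 4, itMax = 2, seed = 1)
#' bestResults(r)
#' @export
bestResults <- function(results) {
  groups <- split(results, list(results$dataset, results$mode), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(-g$testAccuracy, g$L), ]
    g[1, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
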