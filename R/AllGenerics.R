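#' @rdname pcaTransform
#' @export
setGeneric("pcaTransform", function(model, X) standardGeneric("pcaTransform"))

#' @rdname metricsTable
#' @export
setGeneric("metricsTable", function(object, ...) standardGeneric("metricsTable"))

#' @rdname trainIndices
#' @export
setGeneric("trainIndices", function(object) standardGeneric("trainIndices"))

#' @rdname trainIndices
#' @export
setGeneric("testIndices", function(object) standardGeneric("testIndices"))

#' @rdname elm-accessors
#' @export
setGeneric("inputWeights", function(object) standardGeneric("inputWeights"))

#' @rdname elm-accessors
#' @export
setGeneric("hiddenBiases", function(object) standardGeneric("hiddenBiases"))

#' @rdname elm-accessors
#' @export
setGeneric("outputWeights", function(object) standardGeneric("outputWeights"))

#' @rdname gwo-accessors
#' @export
setGeneric("bestPosition", function(object) standardGeneric("bestPosition"))

#' @rdname gwo-accessors
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))

#' @rdname gwo-accessors
#' @export
setGeneric("fitnessTrace", function(object) standardGeneric("fitnessTrace"))

#' @rdname explainedVariance
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))

#' @rdname explainedVariance
#' @export
setGeneric("principalComponents", function(object) standardGeneric("principalComponents"))
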