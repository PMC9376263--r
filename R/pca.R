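#' Fit a principal-component model
#'
#' Mean-centres `X` and eigendecomposes the sample Gram matrix
#' `Xc %*% t(Xc)` (the N x N side), which is far cheaper than an SVD of
#' the full matrix when features vastly outnumber samples -- the usual
#' situation for 32,400-dimensional HOG descriptors.  Feature-space
#' components are recovered as `t(Xc) %*% u / sqrt(lambda)` and are
#' orthonormal.  With `k = "all"` every component with positive
#' variance is kept: at most `nrow(X) - 1`, and exactly that for
#' generic full-rank data.  Signs are fixed so each component's
#' largest-magnitude loading is positive, making the fit deterministic.
#'
#' @param X numeric matrix, samples in rows.
#' @param k number of components, or `"all"` (default).
#' @return a [PCAModel-class] object.
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' fitPCA(X)                    # 7 components
#' @export
fitPCA <- function(X, k = "all") {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  G <- tcrossprod(Xc)
  e <- eigen(G, symmetric = TRUE)
  lam <- e$values
  # relative cutoff, plus an absolute floor at the level of the rounding
  # noise centering introduces (so identical rows report rank 0)
  eps <- .Machine$double.eps
  tol <- max(lam[1], 0) * length(lam) * eps * 100 +
    (eps * (sqrt(sum(X^2)) + 1))^2 * nrow(X)
  nPos <- sum(lam > tol)
  if (identical(k, "all")) {
    k <- nPos
  } else {
    k <- as.integer(k)
    if (k > nPos)
      stop(sprintf("k = %d exceeds the attainable rank %d", k, nPos))
  }
  if (k == 0L) {
    comps <- matrix(0, 0L, ncol(X))
  } else {
    s <- sqrt(lam[seq_len(k)])
    V <- crossprod(Xc, e$vectors[, seq_len(k), drop = FALSE])
    V <- sweep(V, 2L, s, "/")
    # deterministic sign: largest-|loading| coordinate is positive
    flip <- vapply(seq_len(k), function(j) {
      v <- V[, j]
      sign(v[which.max(abs(v))])
    }, numeric(1))
    V <- sweep(V, 2L, ifelse(flip == 0, 1, flip), "*")
    comps <- t(V)
  }
  new("PCAModel", mean = mu, components = comps,
      explainedVariance = if (k) lam[seq_len(k)] / (nrow(X) - 1) else numeric(),
      nSamples = nrow(X))
}

#' @rdname explainedVariance
#' @param object a [PCAModel-class] object.
#' @return `explainedVariance`: per-component variances (decreasing);
#'   `principalComponents`: the k x nFeatures orthonormal basis.
#' @export
setMethod("explainedVariance", "PCAModel",
          function(object) object@explainedVariance)

#' PCA model accessors
#'
#' @rdname explainedVariance
#' @export
setMethod("principalComponents", "PCAModel",
          function(object) object@components)

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components x %d features (fit on %d samples)\n",
              nrow(object@components), ncol(object@components),
              object@nSamples))
  if (length(object@explainedVariance))
    cat(sprintf("  variance retained: %.4g (top component %.4g)\n",
                sum(object@explainedVariance), object@explainedVariance[1]))
})

#' Project data onto fitted principal components
#'
#' Computes `(X - mean) %*% t(components)`.
#'
#' @param model a [PCAModel-class] object.
#' @param X numeric matrix with the model's feature count.
#' @return numeric score matrix, `nrow(X)` x k.
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' m <- fitPCA(X, k = 3)
#' dim(pcaTransform(m, X))
#' @rdname pcaTransform
#' @export
setMethod("pcaTransform", "PCAModel", function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@mean))
    stop(sprintf("X has %d columns but the model expects %d",
                 ncol(X), length(model@mean)))
  sweep(X, 2L, model@mean) %*% t(model@components)
})

#' Fit-and-transform a feature matrix, whole-dataset or train-only
#'
#' With `fitOn = "all"` (the default experimental protocol) the PCA is
#' fitted on every row before any train/test split, reproducing the
#' whole-dataset shapes (e.g. 950 samples -> 949 components); note this
#' lets test rows influence the basis.  `fitOn = "train"` fits on the
#' training rows of `split` only and then transforms all rows -- the
#' leakage-free alternative.
#'
#' @param X numeric feature matrix.
#' @param k components to keep, or `"all"`.
#' @param fitOn `"all"` or `"train"`.
#' @param split a [DatasetSplit-class], required when `fitOn = "train"`.
#' @return list with `scores` (transformed matrix) and `model`.
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' fitTransformPCA(X, k = 3)$scores |> dim()
#' @export
fitTransformPCA <- function(X, k = "all", fitOn = c("all", "train"),
                            split = NULL) {
  fitOn <- match.arg(fitOn)
  if (fitOn == "train") {
    if (is.null(split)) stop("'split' is required when fitOn = \"train\"")
    model <- fitPCA(X[trainIndices(split), , drop = FALSE], k)
  } else {
    model <- fitPCA(X, k)
  }
  list(scores = pcaTransform(model, X), model = model)
}
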