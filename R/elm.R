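#' Random ELM input weights and hidden biases
#'
#' Uniform draws in the standard ELM boxes: input weights in [-1, 1],
#' hidden biases in [0, 1].  Reproducible for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param L number of hidden nodes.
#' @param n number of input features.
#' @param seed integer RNG seed.
#' @return list with `w` (L x n matrix) and `b` (length-L vector).
#' @examples
#' p <- initRandomParams(5, 3, seed = 1)
#' range(p$w); range(p$b)
#' @export
initRandomParams <- function(L, n, seed) {
  if (L < 1L || n < 1L) stop("'L' and 'n' must be >= 1")
  withr::with_seed(as.integer(seed), {
    list(w = matrix(runif(L * n, -1, 1), nrow = L),
         b = runif(L, 0, 1))
  })
}

#' Hidden-layer output matrix
#'
#' `H[j, i] = g(w_i . x_j + b_i)` with the logistic sigmoid `g`; one
#' row per sample, one column per hidden node, entries in (0, 1).
#'
#' @param X numeric matrix, samples in rows (N x n).
#' @param w input weights, L x n.
#' @param b hidden biases, length L.
#' @return N x L numeric matrix.
#' @examples
#' hiddenMatrix(matrix(0, 1, 2), matrix(0, 1, 2), 0)  # 0.5
#' @export
hiddenMatrix <- function(X, w, b) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(w))
    stop(sprintf("X has %d features but w expects %d", ncol(X), ncol(w)))
  if (length(b) != nrow(w)) stop("one bias per hidden node is required")
  Z <- tcrossprod(X, w)
  sigmoid(sweep(Z, 2L, b, "+"))
}

# Moore-Penrose pseudoinverse solve of A x = B via SVD with a relative
# singular-value cutoff; returns the minimum-norm least-squares solution.
pinvSolve <- function(A, B, rcond = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), ncol(B)))
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  V %*% (crossprod(U, B) / sv$d[keep])
}

#' Solve ELM output weights by Moore-Penrose pseudoinverse
#'
#' Computes `rho = pinv(H) %*% T`, the minimum-norm least-squares
#' solution of `H rho = T`, via SVD with singular values below
#' `rcond` times the largest treated as zero.  An optional ridge term
#' solves `(H'H + ridge I) rho = H'T` instead (off by default: the
#' plain pseudoinverse is the reference formulation).
#'
#' @param H hidden-layer output matrix, N x L.
#' @param Tmat one-hot target matrix, N x m.
#' @param rcond relative singular-value cutoff (default 1e-12).
#' @param ridge optional non-negative ridge penalty (default 0).
#' @return L x m output-weight matrix.
#' @examples
#' H <- matrix(rnorm(9), 3); Tm <- diag(3)
#' max(abs(H %*% solveOutputWeights(H, Tm) - Tm)) < 1e-8
#' @export
solveOutputWeights <- function(H, Tmat, rcond = 1e-12, ridge = 0) {
  H <- as.matrix(H); Tmat <- as.matrix(Tmat)
  if (!all(is.finite(H))) stop("'H' must be finite")
  if (nrow(H) != nrow(Tmat)) stop("'H' and 'Tmat' must have matching rows")
  if (ridge > 0)
    return(solve(crossprod(H) + diag(ridge, ncol(H)), crossprod(H, Tmat)))
  pinvSolve(H, Tmat, rcond)
}

# 0/1 one-hot coding of integer labels 1..m
oneHot <- function(y, m) {
  y <- as.integer(y)
  if (any(y < 1L) || any(y > m)) stop("labels must lie in 1..m")
  Tmat <- matrix(0, length(y), m)
  Tmat[cbind(seq_along(y), y)] <- 1
  Tmat
}

#' Train a basic Extreme Learning Machine
#'
#' Draws random input weights and biases ([initRandomParams()]), forms
#' the hidden-layer matrix, one-hot encodes the labels, and solves the
#' output weights in closed form ([solveOutputWeights()]).  With
#' `L == N` and generic data the network interpolates the training set
#' exactly.
#'
#' @param X numeric feature matrix, samples in rows.
#' @param y integer class labels in 1..m.
#' @param L number of hidden nodes.
#' @param seed integer RNG seed for the random layer.
#' @param nClasses number of classes m (default `max(y)`).
#' @param ridge optional ridge penalty, see [solveOutputWeights()].
#' @return an [ELMModel-class] object.
#' @examples
#' d <- makeFeatureDataset(nPerClass = 20, nClasses = 3, nFeatures = 4,
#'                         separation = 6, seed = 1)
#' m <- trainELM(d$X, d$y, L = 30, seed = 2)
#' mean(predict(m, d$X) == d$y)
#' @export
trainELM <- function(X, y, L, seed, nClasses = max(as.integer(y)),
                     ridge = 0) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("one label per row of 'X' is required")
  nClasses <- as.integer(nClasses)
  p <- initRandomParams(L, ncol(X), seed)
  H <- hiddenMatrix(X, p$w, p$b)
  rho <- solveOutputWeights(H, oneHot(y, nClasses), ridge = ridge)
  new("ELMModel", w = p$w, b = p$b, rho = rho, activation = "sigmoid",
      nClasses = nClasses)
}

#' Predict class labels with an ELM
#'
#' Scores are `hiddenMatrix(X, w, b) %*% rho`; the predicted label is
#' the argmax over the m class scores, ties broken toward the lowest
#' class index.
#'
#' @param object an [ELMModel-class] object.
#' @param newdata numeric feature matrix.
#' @return integer labels in 1..m.
#' @aliases predict,ELMModel-method
#' @export
setMethod("predict", "ELMModel", function(object, newdata) {
  H <- hiddenMatrix(as.matrix(newdata), object@w, object@b)
  max.col(H %*% object@rho, ties.method = "first")
})

#' @rdname elm-accessors
#' @param object an [ELMModel-class] object.
#' @return the requested parameter block.
#' @export
setMethod("inputWeights", "ELMModel", function(object) object@w)

#' ELM model accessors
#' @rdname elm-accessors
#' @export
setMethod("hiddenBiases", "ELMModel", function(object) object@b)

#' @rdname elm-accessors
#' @export
setMethod("outputWeights", "ELMModel", function(object) object@rho)

setMethod("show", "ELMModel", function(object) {
  cat(sprintf("ELMModel: %d hidden nodes, %d inputs, %d classes (%s)\n",
              nrow(object@w), ncol(object@w), object@nClasses,
              object@activation))
})
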