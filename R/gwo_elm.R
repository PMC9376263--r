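#' Flatten ELM parameters into a search-agent vector
#'
#' Layout: the L rows of `w` concatenated (`w[1,1..n], w[2,1..n], ...`)
#' followed by the L biases, giving length `L * (n + 1)`.
#' [decodeAgent()] is the exact inverse.
#'
#' @param w input weights, L x n.
#' @param b hidden biases, length L.
#' @return numeric vector of length `L * (n + 1)`.
#' @examples
#' encodeAgent(matrix(c(0.5, -0.5), 1), 0.25)
#' @export
encodeAgent <- function(w, b) {
  if (length(b) != nrow(w)) stop("one bias per hidden node is required")
  c(as.vector(t(w)), b)
}

#' @rdname encodeAgent
#' @param v agent vector of length `L * (n + 1)`.
#' @param L number of hidden nodes.
#' @param n number of input features.
#' @return `decodeAgent`: list with `w` and `b`.
#' @export
decodeAgent <- function(v, L, n) {
  if (length(v) != L * (n + 1))
    stop(sprintf("agent length %d != L*(n+1) = %d", length(v), L * (n + 1)))
  list(w = matrix(v[seq_len(L * n)], nrow = L, byrow = TRUE),
       b = v[L * n + seq_len(L)])
}

#' Fitness of a search agent
#'
#' Decodes the agent into ELM input weights and biases, solves the
#' output weights on the supplied data, and scores the agent.  The
#' default `"accuracy"` fitness is the fraction of correct
#' classifications; `"mse"` is the negated mean squared one-hot
#' residual (so larger is better for both).  Deterministic: repeated
#' evaluation of the same agent gives the same value.
#'
#' @param v agent vector of length `L * (n + 1)`.
#' @param X numeric feature matrix.
#' @param y integer class labels in 1..m.
#' @param L number of hidden nodes.
#' @param nClasses number of classes m (default `max(y)`).
#' @param type `"accuracy"` (default) or `"mse"`.
#' @return numeric scalar fitness.
#' @examples
#' d <- makeFeatureDataset(nPerClass = 10, nClasses = 2, nFeatures = 3,
#'                         separation = 5, seed = 1)
#' p <- initRandomParams(10, 3, seed = 2)
#' fitnessAccuracy(encodeAgent(p$w, p$b), d$X, d$y, L = 10)
#' @export
fitnessAccuracy <- function(v, X, y, L, nClasses = max(as.integer(y)),
                            type = c("accuracy", "mse")) {
  type <- match.arg(type)
  X <- as.matrix(X); y <- as.integer(y)
  par <- decodeAgent(v, L, ncol(X))
  H <- hiddenMatrix(X, par$w, par$b)
  Tmat <- oneHot(y, nClasses)
  rho <- solveOutputWeights(H, Tmat)
  scores <- H %*% rho
  if (type == "accuracy")
    mean(max.col(scores, ties.method = "first") == y)
  else
    -mean((scores - Tmat)^2)
}

#' Train a GWO-optimized Extreme Learning Machine
#'
#' The hybrid classifier: each search agent encodes a full set of ELM
#' input weights and hidden biases ([encodeAgent()]); Gray Wolf
#' Optimization searches the mixed box ([-1,1] on weight coordinates,
#' [0,1] on bias coordinates) maximising training-set classification
#' accuracy (each evaluation solves the output weights in closed
#' form).  The alpha wolf is then decoded and the final output weights
#' recomputed once from it, yielding the deployable model.
#'
#' @param X numeric training feature matrix (N x n).
#' @param y integer class labels in 1..m.
#' @param L number of hidden nodes.
#' @param nAgents population size (default 50).
#' @param itMax iteration budget (default 100).
#' @param seed integer RNG seed; the whole run is reproducible.
#' @param nClasses number of classes m (default `max(y)`).
#' @param fitness `"accuracy"` (default, the reference behaviour) or
#'   `"mse"`.
#' @return list with `model` (an [ELMModel-class]) and `fit`
#'   (a [GWOFit-class] with the alpha-fitness trace).
#' @examples
#' d <- makeFeatureDataset(nPerClass = 10, nClasses = 3, nFeatures = 4,
#'                         separation = 3, seed = 1)
#' r <- trainGWOELM(d$X, d$y, L = 20, nAgents = 5, itMax = 5, seed = 1)
#' bestFitness(r$fit)
#' @export
trainGWOELM <- function(X, y, L, nAgents = 50L, itMax = 100L, seed = 1L,
                        nClasses = max(as.integer(y)),
                        fitness = c("accuracy", "mse")) {
  fitness <- match.arg(fitness)
  X <- as.matrix(X); y <- as.integer(y)
  if (length(y) != nrow(X)) stop("one label per row of 'X' is required")
  n <- ncol(X)
  dim <- L * (n + 1L)
  lower <- c(rep(-1, L * n), rep(0, L))
  upper <- rep(1, dim)
  fitFun <- function(v) fitnessAccuracy(v, X, y, L, nClasses, fitness)
  gwo <- gwoOptimize(fitFun, lower, upper, dim, nAgents = nAgents,
                     itMax = itMax, seed = seed, maximize = TRUE)
  par <- decodeAgent(bestPosition(gwo), L, n)
  H <- hiddenMatrix(X, par$w, par$b)
  rho <- solveOutputWeights(H, oneHot(y, as.integer(nClasses)))
  model <- new("ELMModel", w = par$w, b = par$b, rho = rho,
               activation = "sigmoid", nClasses = as.integer(nClasses))
  list(model = model, fit = gwo)
}
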