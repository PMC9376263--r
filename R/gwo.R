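#' Exploration coefficient schedule
#'
#' The control parameter `a = 2 - it * (2 / itMax)`: a linear decay
#' from 2 (pure exploration) at iteration 0 to 0 (pure exploitation)
#' at the final iteration.
#'
#' @param it current iteration, `0 <= it <= itMax`.
#' @param itMax iteration budget, >= 1.
#' @return numeric scalar in [0, 2].
#' @examples
#' decayA(0, 100); decayA(50, 100); decayA(100, 100)
#' @export
decayA <- function(it, itMax) {
  if (itMax < 1) stop("'itMax' must be >= 1")
  if (it < 0 || it > itMax) stop("'it' must lie in [0, itMax]")
  2 - it * (2 / itMax)
}

#' Stochastic coefficient vectors A and C
#'
#' Per-dimension draws `A = 2a r1 - a` and `C = 2 r2` with
#' `r1, r2 ~ Uniform[0, 1]`, so `A` lies in `[-a, a]` and `C` in
#' `[0, 2]` elementwise.  Fresh draws are taken on every call (per
#' leader, per agent, per iteration).
#'
#' @param a current exploration coefficient, in [0, 2].
#' @param dim dimensionality.
#' @param r1,r2 optional fixed uniforms (length `dim`) for
#'   deterministic checks; drawn when NULL.
#' @return list with numeric vectors `A` and `C`.
#' @examples
#' coefficientVectors(2, 3)
#' @export
coefficientVectors <- function(a, dim, r1 = NULL, r2 = NULL) {
  if (a < 0 || a > 2) stop("'a' must lie in [0, 2]")
  if (is.null(r1)) r1 <- runif(dim)
  if (is.null(r2)) r2 <- runif(dim)
  list(A = 2 * a * r1 - a, C = 2 * r2)
}

#' One position update toward the three leaders
#'
#' For each leader k in {alpha, beta, delta}, with independent
#' coefficient draws: `D_k = |C_k * X_k - x|` and
#' `X'_k = X_k - A_k * D_k`; the new position is the mean
#' `(X'_alpha + X'_beta + X'_delta) / 3`, clipped to the search box.
#' With `a = 0` every `A_k` vanishes and the update lands on the
#' leaders' centroid.
#'
#' @param x current position.
#' @param leaders list of three leader positions (alpha, beta, delta).
#' @param a exploration coefficient.
#' @param lower,upper box bounds (scalars or per-dimension vectors).
#' @param draws optional list of three `list(r1, r2)` fixed uniforms,
#'   one per leader, for deterministic checks.
#' @return numeric vector, the clipped new position.
#' @examples
#' updatePosition(c(0, 0), list(c(1, 1), c(1, -1), c(-1, 1)), a = 0,
#'                lower = -1, upper = 1)
#' @export
updatePosition <- function(x, leaders, a, lower, upper, draws = NULL) {
  stopifnot(length(leaders) == 3L)
  d <- length(x)
  acc <- numeric(d)
  for (k in 1:3) {
    Xk <- leaders[[k]]
    if (length(Xk) != d) stop("leader dimension mismatch")
    co <- if (is.null(draws)) coefficientVectors(a, d)
          else coefficientVectors(a, d, draws[[k]]$r1, draws[[k]]$r2)
    Dk <- abs(co$C * Xk - x)
    acc <- acc + (Xk - co$A * Dk)
  }
  pmin(pmax(acc / 3, lower), upper)
}

# cascade leader update (alpha > beta > delta on strict improvement);
# agents are visited in index order so ties keep the earlier agent
updateLeaders <- function(leaders, positions, fitness) {
  for (i in seq_along(fitness)) {
    f <- fitness[i]
    if (f > leaders$fa) {
      leaders[c("xd", "fd")] <- leaders[c("xb", "fb")]
      leaders[c("xb", "fb")] <- leaders[c("xa", "fa")]
      leaders$xa <- positions[i, ]; leaders$fa <- f
    } else if (f > leaders$fb) {
      leaders[c("xd", "fd")] <- leaders[c("xb", "fb")]
      leaders$xb <- positions[i, ]; leaders$fb <- f
    } else if (f > leaders$fd) {
      leaders$xd <- positions[i, ]; leaders$fd <- f
    }
  }
  leaders
}

#' Gray Wolf Optimization over a box
#'
#' Population metaheuristic: agents ("wolves") update their positions
#' toward the three best solutions found so far (alpha, beta, delta)
#' under stochastic coefficients whose amplitude decays linearly over
#' the run ([decayA()]).  The loop: initialise agents uniformly in the
#' box, evaluate, rank the leaders, then for `itMax` iterations update
#' every position ([updatePosition()]), re-evaluate, and promote
#' strictly better agents into the leader ranks.  The alpha fitness
#' trace is therefore monotone non-decreasing.  Maximisation is the
#' native sense; set `maximize = FALSE` to minimise (the trace is
#' still reported on the caller's scale).
#'
#' @param fitness function taking a position vector, returning a
#'   finite scalar.
#' @param lower,upper per-dimension box bounds (scalars are recycled
#'   to `dim`).
#' @param dim dimensionality of the search space.
#' @param nAgents population size (default 50), at least 3.
#' @param itMax iteration budget (default 100).
#' @param seed integer RNG seed; the run is fully reproducible.
#' @param maximize logical (default TRUE).
#' @return a [GWOFit-class] object.
#' @examples
#' fit <- gwoOptimize(function(x) -sum(x^2), lower = -1, upper = 1,
#'                    dim = 5, nAgents = 10, itMax = 20, seed = 1)
#' bestFitness(fit)
#' @export
gwoOptimize <- function(fitness, lower, upper, dim, nAgents = 50L,
                        itMax = 100L, seed = 1L, maximize = TRUE) {
  nAgents <- as.integer(nAgents); itMax <- as.integer(itMax)
  if (nAgents < 3L)
    stop("'nAgents' must be >= 3 (alpha, beta and delta must be distinct slots)")
  if (itMax < 1L) stop("'itMax' must be >= 1")
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (!all(is.finite(lower)) || !all(is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper in every dimension")
  f <- if (maximize) fitness else function(x) -fitness(x)

  withr::with_seed(as.integer(seed), {
    positions <- matrix(runif(nAgents * dim), nAgents, dim)
    positions <- sweep(sweep(positions, 2L, upper - lower, "*"), 2L,
                       lower, "+")
    evalAll <- function(P) {
      v <- vapply(seq_len(nrow(P)), function(i) f(P[i, ]), numeric(1))
      bad <- which(!is.finite(v))
      if (length(bad))
        stop(sprintf("non-finite fitness for agent %d", bad[1]))
      v
    }
    fit <- evalAll(positions)
    leaders <- updateLeaders(
      list(xa = NULL, fa = -Inf, xb = NULL, fb = -Inf,
           xd = NULL, fd = -Inf), positions, fit)
    trace <- numeric(itMax + 1L)
    trace[1L] <- leaders$fa
    for (it in seq_len(itMax)) {
      a <- decayA(it, itMax)
      lead <- list(leaders$xa, leaders$xb, leaders$xd)
      for (i in seq_len(nAgents))
        positions[i, ] <- updatePosition(positions[i, ], lead, a,
                                         lower, upper)
      fit <- evalAll(positions)
      leaders <- updateLeaders(leaders, positions, fit)
      trace[it + 1L] <- leaders$fa
    }
    new("GWOFit", bestPosition = leaders$xa,
        bestFitness = if (maximize) leaders$fa else -leaders$fa,
        trace = if (maximize) trace else -trace,
        nAgents = nAgents, itMax = itMax, maximize = maximize)
  })
}

#' @rdname gwo-accessors
#' @param object a [GWOFit-class] object.
#' @return `bestPosition`: the alpha position; `bestFitness`: its
#'   fitness; `fitnessTrace`: alpha fitness after initialisation and
#'   after each iteration.
#' @export
setMethod("bestPosition", "GWOFit", function(object) object@bestPosition)

#' GWO result accessors
#' @rdname gwo-accessors
#' @export
setMethod("bestFitness", "GWOFit", function(object) object@bestFitness)

#' @rdname gwo-accessors
#' @export
setMethod("fitnessTrace", "GWOFit", function(object) object@trace)

setMethod("show", "GWOFit", function(object) {
  cat(sprintf(
    "GWOFit: %d agents, %d iterations, best fitness %.6g (dim %d)\n",
    object@nAgents, object@itMax, object@bestFitness,
    length(object@bestPosition)))
})
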