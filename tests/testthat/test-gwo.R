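test_that("the exploration coefficient decays linearly from 2 to 0", {
  expect_equal(decayA(0, 100), 2)
  expect_equal(decayA(100, 100), 0)
  expect_equal(decayA(50, 100), 1)
  expect_error(decayA(1, 0), "itMax")
  expect_error(decayA(-1, 10), "it")
})

test_that("coefficient vectors respect their analytic ranges", {
  expect_equal(coefficientVectors(0, 5)$A, rep(0, 5))   # a = 0 forces A = 0
  co <- coefficientVectors(2, 3, r1 = rep(1, 3), r2 = rep(0.5, 3))
  expect_equal(co$A, rep(2, 3))
  expect_equal(co$C, rep(1, 3))

  set.seed(30)
  draws <- replicate(100, unlist(coefficientVectors(1.3, 1000)))
  A <- draws[1:1000, ]; C <- draws[1001:2000, ]
  expect_true(all(A >= -1.3 & A <= 1.3))
  expect_true(all(C >= 0 & C <= 2))
  expect_error(coefficientVectors(2.5, 2), "a")
})

test_that("the position update follows the three-leader mean formula", {
  # identical leaders and A = 0: fixed point
  x <- c(0.2, -0.4)
  leaders <- list(x, x, x)
  expect_equal(updatePosition(x, leaders, a = 0, lower = -1, upper = 1), x)

  # a = 0 collapses the update to the leaders' centroid
  L3 <- list(c(1, 0), c(0, 1), c(-1, -1))
  expect_equal(updatePosition(c(0.5, 0.5), L3, a = 0, lower = -1, upper = 1),
               c(0, 0))

  # 1-d hand-worked case with pinned uniforms:
  # leader X=0.8, x=0.2, a=1, r1=0.75, r2=0.5 for every leader
  # A = 2*1*0.75 - 1 = 0.5 ; C = 1 ; D = |1*0.8 - 0.2| = 0.6
  # X' = 0.8 - 0.5*0.6 = 0.5 for each leader -> mean 0.5
  draws <- replicate(3, list(r1 = 0.75, r2 = 0.5), simplify = FALSE)
  expect_equal(
    updatePosition(0.2, list(0.8, 0.8, 0.8), a = 1, lower = -1, upper = 1,
                   draws = draws), 0.5)

  # clipping keeps the result inside the box
  expect_equal(
    updatePosition(0, list(5, 5, 5), a = 0, lower = -1, upper = 1), 1)
})

test_that("optimisation improves the sphere function across seeds", {
  for (s in 1:20) {
    fit <- gwoOptimize(function(x) -sum(x^2), lower = -1, upper = 1,
                       dim = 5, nAgents = 50, itMax = 100, seed = s)
    tr <- fitnessTrace(fit)
    expect_true(all(diff(tr) >= 0))                 # monotone alpha trace
    expect_gte(bestFitness(fit), tr[1])
    expect_lt(sum(bestPosition(fit)^2), 0.05)       # near the optimum
    expect_true(all(abs(bestPosition(fit)) <= 1))
  }
})

test_that("positions stay inside the box at every iteration", {
  seen <- list()
  probe <- function(x) {
    seen[[length(seen) + 1L]] <<- x
    -sum((x - 0.3)^2)
  }
  invisible(gwoOptimize(probe, lower = c(-1, 0), upper = c(1, 2), dim = 2,
                        nAgents = 8, itMax = 30, seed = 4))
  P <- do.call(rbind, seen)
  expect_true(all(P[, 1] >= -1 & P[, 1] <= 1))
  expect_true(all(P[, 2] >= 0 & P[, 2] <= 2))
})

test_that("leader bookkeeping follows the strict-improvement contract", {
  # constant fitness: alpha never changes after initialisation
  fit <- gwoOptimize(function(x) 1, lower = 0, upper = 1, dim = 3,
                     nAgents = 5, itMax = 10, seed = 2)
  expect_equal(fitnessTrace(fit), rep(1, 11))

  # a single round still returns the best agent seen
  f1 <- gwoOptimize(function(x) -sum(x^2), lower = -1, upper = 1, dim = 2,
                    nAgents = 10, itMax = 1, seed = 3)
  expect_length(fitnessTrace(f1), 2L)
  expect_gte(fitnessTrace(f1)[2], fitnessTrace(f1)[1])

  expect_error(gwoOptimize(function(x) 1, 0, 1, dim = 2, nAgents = 2,
                           itMax = 1, seed = 1), "nAgents")
  expect_error(gwoOptimize(function(x) NaN, 0, 1, dim = 2, nAgents = 3,
                           itMax = 1, seed = 1), "non-finite")
  expect_error(gwoOptimize(function(x) 1, 1, 0, dim = 2, nAgents = 3,
                           itMax = 1, seed = 1), "bounds")
})

test_that("minimisation negates the fitness transparently", {
  fit <- gwoOptimize(function(x) sum(x^2), lower = -1, upper = 1, dim = 4,
                     nAgents = 20, itMax = 50, seed = 6, maximize = FALSE)
  expect_lt(bestFitness(fit), 0.05)
  expect_true(all(diff(fitnessTrace(fit)) <= 0))   # non-increasing when minimising
  expect_identical(gwoOptimize(function(x) sum(x^2), -1, 1, dim = 4,
                               nAgents = 20, itMax = 50, seed = 6,
                               maximize = FALSE)@bestPosition,
                   bestPosition(fit))              # reproducible per seed
})
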