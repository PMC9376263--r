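test_that("random initialisation is reproducible and box-bounded", {
  p1 <- initRandomParams(300, 949, seed = 7)
  p2 <- initRandomParams(300, 949, seed = 7)
  expect_identical(p1, p2)
  expect_identical(dim(p1$w), c(300L, 949L))
  expect_length(p1$b, 300L)

  big <- initRandomParams(1000, 1000, seed = 8)   # 1e6 weight draws
  expect_true(all(big$w >= -1 & big$w <= 1))
  expect_true(all(big$b >= 0 & big$b <= 1))
  # draws must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(initRandomParams(3, 3, seed = 99)); after <- runif(1)
  expect_identical(before, after)
})

test_that("hidden matrix applies the sigmoid to w.x + b", {
  H <- hiddenMatrix(matrix(0, 1, 2), matrix(0, 1, 2), 0)
  expect_equal(H, matrix(0.5, 1, 1))

  # hand-computed 2x2 case
  X <- matrix(c(1, -1, 0.5, 2), 2, byrow = TRUE)
  w <- matrix(c(0.2, -0.3, 0.7, 0.1), 2, byrow = TRUE)
  b <- c(0.4, -0.2)
  expected <- 1 / (1 + exp(-(X %*% t(w) + rep(b, each = 2))))
  expect_equal(hiddenMatrix(X, w, b), expected, tolerance = 1e-12)

  set.seed(2)
  H2 <- hiddenMatrix(matrix(rnorm(50), 10), matrix(runif(15, -1, 1), 3), runif(3))
  expect_true(all(H2 > 0 & H2 < 1))
  expect_error(hiddenMatrix(matrix(0, 2, 3), matrix(0, 2, 2), c(0, 0)),
               "features")
})

test_that("output weights solve the least-squares problem via pinv", {
  set.seed(3)
  H <- matrix(rnorm(16), 4)
  Tm <- diag(4)[, 1:3]
  rho <- solveOutputWeights(H, Tm)
  expect_equal(rho, solve(H, Tm), tolerance = 1e-8)   # invertible case

  expect_equal(solveOutputWeights(H, matrix(0, 4, 2)), matrix(0, 4, 2))

  # minimum-residual optimality under random perturbations
  H2 <- matrix(rnorm(30 * 10), 30)
  T2 <- matrix(rnorm(30 * 3), 30)
  rho2 <- solveOutputWeights(H2, T2)
  res0 <- sum((H2 %*% rho2 - T2)^2)
  for (i in 1:25) {
    delta <- matrix(rnorm(30, sd = 0.01), 10, 3)
    expect_gte(sum((H2 %*% (rho2 + delta) - T2)^2), res0)
  }

  # agreement with an independent pseudoinverse implementation
  expect_equal(rho2, MASS::ginv(H2) %*% T2, tolerance = 1e-8)
  expect_error(solveOutputWeights(matrix(c(1, NA), 1), matrix(1, 1)), "finite")
})

test_that("L == N gives exact interpolation of generic training data", {
  d <- makeFeatureDataset(nPerClass = 8, nClasses = 5, nFeatures = 10,
                          separation = 1, seed = 21)   # heavily overlapping
  m <- trainELM(d$X, d$y, L = nrow(d$X), seed = 5)
  expect_equal(mean(predict(m, d$X) == d$y), 1)
  H <- hiddenMatrix(d$X, inputWeights(m), hiddenBiases(m))
  Tm <- diag(5)[d$y, ]
  expect_lt(max(abs(H %*% outputWeights(m) - Tm)), 1e-6)
})

test_that("training is seed-deterministic and separates easy blobs", {
  d <- separableBlobs(nPerClass = 60, nClasses = 2, nFeatures = 4)
  m1 <- trainELM(d$X, d$y, L = 100, seed = 9)
  m2 <- trainELM(d$X, d$y, L = 100, seed = 9)
  expect_identical(outputWeights(m1), outputWeights(m2))
  expect_gte(mean(predict(m1, d$X) == d$y), 0.99)

  # the hidden-node sweep of the experimental protocol all train cleanly
  models <- lapply(seq(100, 300, by = 25), function(L)
    trainELM(d$X, d$y, L = L, seed = 1))
  expect_length(unique(vapply(models, function(m) nrow(inputWeights(m)),
                              integer(1))), 9L)
})

test_that("prediction takes the argmax with low-index tie-breaking", {
  m <- new("ELMModel", w = matrix(0, 1, 2), b = 0,
           rho = matrix(c(1, 1), 1), activation = "sigmoid", nClasses = 2L)
  # both class scores equal 0.5 -> tie resolved to class 1
  expect_identical(predict(m, matrix(0, 3, 2)), rep(1L, 3))

  d <- separableBlobs(nPerClass = 10)
  mod <- trainELM(d$X, d$y, L = 20, seed = 1)
  onerow <- d$X[1, , drop = FALSE]
  expect_identical(predict(mod, onerow[rep(1, 5), ]),
                   rep(predict(mod, onerow), 5))
  expect_error(predict(mod, d$X[, 1:2]), "features")
})
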