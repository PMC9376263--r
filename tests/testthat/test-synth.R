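test_that("image generation is reproducible and grade-aware", {
  i1 <- makeFundusImage(grade = 3, seed = 9, side = 128)
  i2 <- makeFundusImage(grade = 3, seed = 9, side = 128)
  expect_identical(i1, i2)
  expect_identical(dim(i1), c(128L, 128L, 3L))
  expect_true(all(i1 >= 0 & i1 <= 1))

  # grade 1 carries no lesions at all
  healthy <- makeFundusImage(grade = 1, seed = 10, side = 128)
  expect_identical(attr(healthy, "lesionPixels"), 0L)

  # same seed, extreme grades: proliferative has strictly more lesion pixels
  g1 <- makeFundusImage(grade = 1, seed = 11, side = 128)
  g5 <- makeFundusImage(grade = 5, seed = 11, side = 128)
  expect_gt(attr(g5, "lesionPixels"), attr(g1, "lesionPixels"))

  expect_error(makeFundusImage(grade = 0, seed = 1), "grade")
})

test_that("expected lesion burden increases strictly with grade", {
  perGrade <- sapply(1:5, function(g) {
    mean(sapply(1:50, function(s)
      attr(makeFundusImage(g, seed = 500 + s, side = 96), "lesionPixels")))
  })
  expect_true(all(diff(perGrade) > 0))
  expect_identical(perGrade[1], 0)
})

test_that("image datasets are balanced over the five grades", {
  d <- makeImageDataset(nPerClass = 2, side = 64, seed = 3)
  expect_length(d$images, 10L)
  expect_identical(as.vector(table(d$labels)), rep(2L, 5))
  expect_identical(d$labels, rep(1:5, each = 2))
  expect_error(makeImageDataset(0), "nPerClass")
})

test_that("feature tables honour separation, shape and determinism", {
  d <- makeFeatureDataset(nPerClass = 30, nClasses = 5, nFeatures = 10,
                          separation = 3, seed = 12)
  expect_identical(dim(d$X), c(150L, 10L))
  expect_identical(as.vector(table(d$y)), rep(30L, 5))
  expect_identical(d, makeFeatureDataset(nPerClass = 30, nClasses = 5,
                                         nFeatures = 10, separation = 3,
                                         seed = 12))

  # empirical pairwise mean distances concentrate near 'separation'
  mu <- t(sapply(1:5, function(c) colMeans(d$X[d$y == c, ])))
  dd <- as.vector(dist(mu))
  expect_true(all(abs(dd - 3) < 0.8))

  expect_error(makeFeatureDataset(10, nFeatures = 3), "nFeatures")
  expect_error(makeFeatureDataset(10, separation = -1), "separation")
})

test_that("separation drives classifier accuracy from chance to ceiling", {
  # separation 0: all classes identical, expected accuracy ~ 1/K
  d0 <- makeFeatureDataset(nPerClass = 60, nClasses = 5, nFeatures = 10,
                           separation = 0, seed = 13)
  sp <- stratifiedSplit(d0$y, 0.8, seed = 1)
  m0 <- trainELM(d0$X[trainIndices(sp), ], d0$y[trainIndices(sp)],
                 L = 40, seed = 1)
  acc0 <- mean(predict(m0, d0$X[testIndices(sp), ]) ==
                 d0$y[testIndices(sp)])
  expect_lt(acc0, 0.45)

  # separation 10: essentially separable for any reasonable classifier
  accs <- sapply(1:5, function(s) {
    d <- makeFeatureDataset(nPerClass = 60, nClasses = 5, nFeatures = 10,
                            separation = 10, seed = 20 + s)
    spl <- stratifiedSplit(d$y, 0.8, seed = s)
    m <- trainELM(d$X[trainIndices(spl), ], d$y[trainIndices(spl)],
                  L = 40, seed = s)
    mean(predict(m, d$X[testIndices(spl), ]) == d$y[testIndices(spl)])
  })
  expect_true(all(accs >= 0.99))
})
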