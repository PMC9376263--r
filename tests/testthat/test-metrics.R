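test_that("binary metrics reproduce both reported binary rows exactly", {
  t1 <- metricsTable(binaryMetrics(tp = 151, fp = 1, fn = 0, tn = 38))
  expect_equal(unlist(t1),
               c(accuracy = 99.47, precision = 99.34, recall = 100.00,
                 specificity = 97.44, mcc = 98.38, f_measure = 99.67,
                 g_mean = 99.67))

  t2 <- metricsTable(binaryMetrics(tp = 70, fp = 0, fn = 1, tn = 33))
  expect_equal(unlist(t2),
               c(accuracy = 99.04, precision = 100.00, recall = 98.59,
                 specificity = 100.00, mcc = 97.82, f_measure = 99.29,
                 g_mean = 99.29))
})

test_that("the reported binary rows pin down the confusion counts uniquely", {
  row1 <- c(accuracy = 99.47, precision = 99.34, recall = 100.00,
            specificity = 97.44, mcc = 98.38)
  found1 <- searchBinaryCounts(190, row1)
  expect_identical(nrow(found1), 1L)
  expect_equal(found1[1, ], c(tp = 151, fp = 1, fn = 0, tn = 38))

  row2 <- c(accuracy = 99.04, precision = 100.00, recall = 98.59,
            specificity = 100.00, mcc = 97.82)
  found2 <- searchBinaryCounts(104, row2)
  expect_identical(nrow(found2), 1L)
  expect_equal(found2[1, ], c(tp = 70, fp = 0, fn = 1, tn = 33))
})

test_that("one-vs-rest reduction satisfies the count identities", {
  M <- balancedConfusion(5, 38, 18)
  ovr <- ovrCounts(M)
  expect_equal(sum(ovr$tp), 172)
  expect_equal(sum(ovr$fp), 18)
  expect_equal(sum(ovr$fn), 18)
  expect_equal(sum(ovr$tn), 742)        # K*n - n - e with n = 190, e = 18

  D <- diag(c(3, 4, 5))
  ovrD <- ovrCounts(D)
  expect_true(all(ovrD$fp == 0) && all(ovrD$fn == 0))

  # 2x2 reduction row for class 2 matches the direct binary counts
  M2 <- matrix(c(30, 5, 2, 60), 2, byrow = TRUE)
  o2 <- ovrCounts(M2)
  expect_equal(unlist(o2[2, c("tp", "fp", "fn", "tn")]),
               c(tp = 60, fp = 5, fn = 2, tn = 30))
  expect_error(ovrCounts(matrix(0, 2, 3)), "square")
})

test_that("multi-class aggregation reproduces both reported 5-class rows", {
  M1 <- balancedConfusion(5, 38, 18)
  expect_equal(unlist(metricsTable(multiclassMetrics(M1))),
               c(accuracy = 96.21, precision = 90.53, recall = 90.53,
                 specificity = 97.63, mcc = 88.16, f_measure = 90.53,
                 g_mean = 90.53))

  # class totals (34, 5, 34, 19, 12) with e = 10 errors
  M2 <- diag(c(34, 5, 34, 19, 12))
  errs <- rbind(c(1, 2, 2), c(3, 4, 3), c(4, 5, 3), c(5, 1, 2))
  for (i in seq_len(nrow(errs))) {
    M2[errs[i, 1], errs[i, 1]] <- M2[errs[i, 1], errs[i, 1]] - errs[i, 3]
    M2[errs[i, 1], errs[i, 2]] <- M2[errs[i, 1], errs[i, 2]] + errs[i, 3]
  }
  expect_equal(sum(M2) - sum(diag(M2)), 10)
  expect_equal(unlist(metricsTable(multiclassMetrics(M2))),
               c(accuracy = 96.15, precision = 90.38, recall = 90.38,
                 specificity = 97.60, mcc = 87.98, f_measure = 90.38,
                 g_mean = 90.38))

  perfect <- diag(rep(10, 5))
  expect_equal(unlist(metricsTable(multiclassMetrics(perfect))),
               c(accuracy = 100, precision = 100, recall = 100,
                 specificity = 100, mcc = 100, f_measure = 100,
                 g_mean = 100))
  expect_error(multiclassMetrics(matrix(1, 2, 2)), "K >= 3")
})

test_that("closed-form identities hold for balanced matrices with e errors", {
  set.seed(60)
  for (i in 1:10) {
    K <- sample(3:6, 1)
    perClass <- sample(10:60, 1)
    e <- sample(0:(perClass - 1), 1)
    M <- balancedConfusion(K, perClass, e, seed = i)
    n <- K * perClass
    rep <- multiclassMetrics(M)
    expect_equal(unname(rep@metrics["precision"]), (n - e) / n)
    expect_equal(unname(rep@metrics["recall"]), (n - e) / n)
    expect_equal(unname(rep@metrics["specificity"]),
                 (K * n - n - e) / (K * n - n))
    expect_equal(unname(rep@metrics["accuracy"]), (K * n - 2 * e) / (K * n))
  }
})

test_that("binary reduction and direct computation agree on 2x2 problems", {
  set.seed(61)
  truth <- sample(1:2, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.85, truth, 3 - truth)
  M <- confusionMatrix(truth, pred, 2)
  direct <- binaryMetrics(tp = M[2, 2], fp = M[1, 2], fn = M[2, 1],
                          tn = M[1, 1])
  viaEval <- evaluatePredictions(truth, pred, mode = "binary")
  expect_equal(direct@metrics, viaEval@metrics)

  perfectRep <- binaryMetrics(tp = 10, fp = 0, fn = 0, tn = 5)
  expect_true(all(unlist(metricsTable(perfectRep)) == 100))
})

test_that("zero denominators are flagged as undefined, never silent zeros", {
  w1 <- capture_warnings(r <- binaryMetrics(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_true(any(grepl("precision undefined", w1)))
  expect_true(is.na(r@metrics["precision"]))
  w2 <- capture_warnings(r2 <- binaryMetrics(tp = 5, fp = 0, fn = 0, tn = 0))
  expect_true(any(grepl("specificity undefined", w2)))
  expect_true(is.na(r2@metrics["specificity"]))
})

test_that("percentages round half away from zero at two decimals", {
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(-0.125, 2), -0.13)
  expect_equal(roundHalfUp(96.205, 2), 96.21)
  # full precision is retained internally
  r <- binaryMetrics(tp = 151, fp = 1, fn = 0, tn = 38)
  expect_equal(unname(r@metrics["accuracy"]), 189 / 190)
})
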