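# small deterministic fixtures shared across test files

# 3x3 ramp used for hand-computed contrast checks
rampImage <- function(lo = 0.4, hi = 0.6, n = 3) {
  matrix(seq(lo, hi, length.out = n * n), n)
}

# tiny labelled blobs with large separation (essentially separable)
separableBlobs <- function(nPerClass = 20, nClasses = 2, nFeatures = 4,
                           seed = 42) {
  makeFeatureDataset(nPerClass = nPerClass, nClasses = nClasses,
                     nFeatures = nFeatures, separation = 8, seed = seed)
}

# brute-force HOG length: enumerate every block position that fits
bruteForceHogLength <- function(shape, params = HOGParams()) {
  cs <- params@cellSide; bs <- params@blockSide; st <- params@blockStride
  nCellR <- shape[1] %/% cs
  nCellC <- shape[2] %/% cs
  count <- 0L
  i <- 1L
  while (i + bs - 1L <= nCellR) {
    j <- 1L
    while (j + bs - 1L <= nCellC) {
      count <- count + 1L
      j <- j + st
    }
    i <- i + st
  }
  count * bs * bs * params@nBins
}

# exhaustive integer search for confusion counts with a given total that
# reproduce a printed row of percentages (2-decimal, half-up)
searchBinaryCounts <- function(total, row) {
  grid <- expand.grid(tp = 0:total, fp = 0:total)
  grid <- grid[grid$tp + grid$fp <= total, ]
  out <- NULL
  for (fn in 0:total) {
    g <- grid[grid$tp + grid$fp + fn <= total, ]
    if (!nrow(g)) next
    tn <- total - g$tp - g$fp - fn
    acc <- roundHalfUp(100 * (g$tp + tn) / total)
    prec <- roundHalfUp(100 * g$tp / (g$tp + g$fp))
    rec <- roundHalfUp(100 * g$tp / (g$tp + fn))
    spec <- roundHalfUp(100 * tn / (tn + g$fp))
    ok <- which(acc == row["accuracy"] & prec == row["precision"] &
                  rec == row["recall"] & spec == row["specificity"])
    for (i in ok) {
      mcc <- roundHalfUp(
        100 * (g$tp[i] * tn[i] - g$fp[i] * fn) /
          sqrt(g$tp[i] + g$fp[i]) / sqrt(g$tp[i] + fn) /
          sqrt(tn[i] + g$fp[i]) / sqrt(tn[i] + fn))
      if (isTRUE(mcc == row["mcc"]))
        out <- rbind(out, c(tp = g$tp[i], fp = g$fp[i], fn = fn, tn = tn[i]))
    }
  }
  out
}

# balanced K-class confusion matrix with the given per-class row total and
# e off-diagonal errors scattered deterministically
balancedConfusion <- function(K, perClass, e, seed = 1) {
  M <- diag(rep(perClass, K))
  withr::with_seed(seed, {
    for (i in seq_len(e)) {
      repeat {
        r <- sample(K, 1); c <- sample(K, 1)
        if (r != c && M[r, r] > 0) break
      }
      M[r, r] <- M[r, r] - 1
      M[r, c] <- M[r, c] + 1
    }
  })
  M
}
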