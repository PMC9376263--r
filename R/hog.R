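#' Construct HOG geometry parameters
#'
#' @param cellSide pixels per cell side (default 8).
#' @param blockSide cells per block side (default 2).
#' @param blockStride block step in cells (default 1).
#' @param nBins orientation bins (default 9).
#' @param signedGradients keep gradient sign, spreading bins over
#'   [0, 360) instead of folding to [0, 180) (default FALSE).
#' @param hysClip L2-Hys clipping level (default 0.2).
#' @return a [HOGParams-class] object.
#' @examples
#' hogLength(c(255, 255), HOGParams())
#' @export
HOGParams <- function(cellSide = 8L, blockSide = 2L, blockStride = 1L,
                      nBins = 9L, signedGradients = FALSE, hysClip = 0.2) {
  new("HOGParams", cellSide = as.integer(cellSide),
      blockSide = as.integer(blockSide),
      blockStride = as.integer(blockStride), nBins = as.integer(nBins),
      signedGradients = signedGradients, blockNorm = "L2-Hys",
      hysClip = hysClip)
}

setMethod("show", "HOGParams", function(object) {
  cat(sprintf(
    "HOGParams: %dpx cells, %dx%d-cell blocks (stride %d), %d %s bins, %s\n",
    object@cellSide, object@blockSide, object@blockSide,
    object@blockStride, object@nBins,
    if (object@signedGradients) "signed" else "unsigned",
    object@blockNorm))
})

# blocks that fit along one axis, or 0 when none do
blocksAlong <- function(nPixels, p) {
  nCells <- nPixels %/% p@cellSide
  nb <- (nCells - p@blockSide) %/% p@blockStride + 1L
  max(nb, 0L)
}

#' Length of a HOG descriptor
#'
#' Closed-form element count of the descriptor for an image of the
#' given shape: blocksRows * blocksCols * blockSide^2 * nBins, where
#' the block grid has `floor(side/cellSide) - blockSide + 1` positions
#' per axis at stride 1.  The default geometry on a 255 x 255 image
#' gives 30 * 30 * 4 * 9 = 32,400 features.
#'
#' @param shape integer vector `c(rows, cols)`.
#' @param params a [HOGParams-class] object.
#' @return integer feature count.
#' @examples
#' hogLength(c(255, 255))       # 32400
#' hogLength(c(16, 16))         # 36
#' @export
hogLength <- function(shape, params = HOGParams()) {
  validObject(params)
  br <- blocksAlong(shape[1], params)
  bc <- blocksAlong(shape[2], params)
  if (br < 1L || bc < 1L)
    stop(sprintf("image too small for one block: need at least %d pixels per side",
                 params@blockSide * params@cellSide))
  as.integer(br * bc * params@blockSide^2 * params@nBins)
}

#' Gradient magnitude and orientation maps
#'
#' Centred differences with kernel [-1, 0, 1] along each axis (edges
#' replicated), returning the gradient magnitude and its orientation in
#' degrees -- folded to [0, 180) for unsigned gradients, [0, 360)
#' otherwise.
#'
#' @param img numeric matrix with values in [0,1].
#' @param signed keep the gradient sign (default FALSE).
#' @return list with numeric matrices `magnitude` and `orientation`.
#' @examples
#' g <- gradientMaps(matrix(rep(seq(0, 1, length.out = 5), 5), 5))
#' @export
gradientMaps <- function(img, signed = FALSE) {
  assertGray(img)
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3L || nc < 3L) stop("'img' must be at least 3x3")
  gx <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  gy <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) * 180 / pi            # (-180, 180]
  ori <- if (signed) ori %% 360 else ori %% 180
  list(magnitude = mag, orientation = ori)
}

#' HOG descriptor of one image
#'
#' Histogram of Oriented Gradients: gradient magnitudes vote into
#' orientation histograms over non-overlapping square pixel cells, with
#' bilinear interpolation between the two nearest bin centres (circular
#' over the orientation range); overlapping blocks of cells are then
#' L2-Hys normalised (L2-normalise, clip at 0.2, renormalise) and
#' concatenated row-major over block positions, cells within a block,
#' and bins within a cell.  Trailing pixels that do not fill a cell are
#' ignored.  The descriptor is invariant to a global intensity offset.
#'
#' @param img numeric matrix with values in [0,1] (a preprocessed
#'   fundus image).
#' @param params a [HOGParams-class] object.
#' @return numeric vector of length `hogLength(dim(img), params)`.
#' @examples
#' img <- preprocessFundus(makeFundusImage(3, seed = 1, side = 128), side = 64)
#' length(hogDescriptor(img))  # hogLength(c(64, 64))
#' @export
hogDescriptor <- function(img, params = HOGParams()) {
  assertGray(img)
  validObject(params)
  p <- params
  nCellR <- nrow(img) %/% p@cellSide
  nCellC <- ncol(img) %/% p@cellSide
  nbR <- blocksAlong(nrow(img), p)
  nbC <- blocksAlong(ncol(img), p)
  if (nbR < 1L || nbC < 1L)
    stop(sprintf("image too small for one block: need at least %d pixels per side",
                 p@blockSide * p@cellSide))

  usedR <- nCellR * p@cellSide
  usedC <- nCellC * p@cellSide
  g <- gradientMaps(img, signed = p@signedGradients)
  mag <- g$magnitude[seq_len(usedR), seq_len(usedC)]
  ori <- g$orientation[seq_len(usedR), seq_len(usedC)]

  span <- if (p@signedGradients) 360 else 180
  binWidth <- span / p@nBins
  # continuous bin coordinate; centres sit at (k + 0.5) * binWidth
  t <- ori / binWidth - 0.5
  lo <- floor(t)
  frac <- t - lo
  b1 <- (lo %% p@nBins) + 1L
  b2 <- (lo + 1) %% p@nBins + 1L

  cellR <- (row(mag) - 1L) %/% p@cellSide      # 0-based cell indices
  cellC <- (col(mag) - 1L) %/% p@cellSide
  cellId <- cellR + nCellR * cellC             # 0-based, column-major
  idx1 <- cellId * p@nBins + b1
  idx2 <- cellId * p@nBins + b2
  w1 <- mag * (1 - frac)
  w2 <- mag * frac

  hist <- numeric(p@nBins * nCellR * nCellC)
  acc <- rowsum(c(w1, w2), group = c(idx1, idx2))
  hist[as.integer(rownames(acc))] <- acc
  cells <- matrix(hist, nrow = p@nBins)   # one column per cell (col-major)

  # gather block sub-vectors: one row per block position (row-major over
  # the block grid), columns ordered cells row-major then bins
  bs <- p@blockSide; st <- p@blockStride
  bi <- rep(seq_len(nbR), each = nbC)          # block row (outer)
  bj <- rep(seq_len(nbC), times = nbR)         # block col (inner)
  B <- matrix(0, nbR * nbC, bs * bs * p@nBins)
  col0 <- 0L
  for (u in seq_len(bs)) {                     # cell row within block
    for (v in seq_len(bs)) {                   # cell col within block
      sub <- cells[, (bi - 1L) * st + u + (((bj - 1L) * st + v) - 1L) * nCellR]
      B[, col0 + seq_len(p@nBins)] <- t(sub)
      col0 <- col0 + p@nBins
    }
  }

  eps2 <- 1e-20                                # keeps zero blocks zero
  B <- B / sqrt(rowSums(B^2) + eps2)
  B <- pmin(B, p@hysClip)
  B <- B / sqrt(rowSums(B^2) + eps2)
  as.vector(t(B))
}

#' HOG descriptors for a set of images
#'
#' @param images list of equally sized numeric matrices in [0,1].
#' @param params a [HOGParams-class] object.
#' @return numeric matrix, one descriptor per row.
#' @examples
#' imgs <- replicate(2, matrix(runif(256), 16), simplify = FALSE)
#' dim(hogDataset(imgs))  # 2 x 36
#' @export
hogDataset <- function(images, params = HOGParams()) {
  if (length(images) == 0L) stop("'images' must not be empty")
  shapes <- vapply(images, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("all images must have the same shape")
  t(vapply(images, hogDescriptor, numeric(hogLength(shapes[, 1], params)),
           params = params))
}
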