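#' Convert a color fundus image to grayscale
#'
#' Collapses an RGB array to a single luminance channel using the
#' ITU-R BT.601 weights 0.2989 R + 0.5870 G + 0.1140 B (the classic
#' `rgb2gray` convention).  Inputs on a 0-255 scale are rescaled to
#' [0,1] first; single-channel input is passed through unchanged apart
#' from the rescale.
#'
#' @param img numeric array `height x width x 3`, numeric matrix, or a
#'   `height x width x 1` array; values in [0,1] or [0,255].
#' @return numeric matrix with values in [0,1].
#' @examples
#' rgb <- array(runif(12), dim = c(2, 2, 3))
#' gray <- toGrayscale(rgb)
#' @export
toGrayscale <- function(img) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("'img' must be a height x width x channels array or a matrix")
  nch <- dim(img)[3L]
  if (!nch %in% c(1L, 3L))
    stop("'img' must have 1 or 3 channels, got ", nch)
  if (anyNA(img) || any(!is.finite(img)))
    stop("'img' must be finite")
  if (max(img) > 1) img <- img / 255
  if (min(img) < 0) stop("negative intensities are not supported")
  out <- if (nch == 1L) img[, , 1L, drop = FALSE]
  else 0.2989 * img[, , 1L, drop = FALSE] +
    0.5870 * img[, , 2L, drop = FALSE] + 0.1140 * img[, , 3L, drop = FALSE]
  clip01(matrix(out, dim(img)[1L], dim(img)[2L]))
}

#' Stretch grayscale contrast between two quantiles
#'
#' Linear intensity rescale mapping the `lowTail` quantile to 0 and the
#' `highTail` quantile to 1, clipping outside (an `imadjust`-style
#' stretch with 1%/99% saturation by default).  The map is monotone, so
#' pixel ordering is preserved.  A constant image is returned unchanged
#' with a warning, since no stretch is defined.
#'
#' @param img numeric matrix with values in [0,1].
#' @param lowTail,highTail saturation quantile fractions,
#'   `0 <= lowTail < highTail <= 1` (defaults 0.01 and 0.99).
#' @return numeric matrix with values in [0,1].
#' @examples
#' m <- matrix(seq(0.4, 0.6, length.out = 9), 3)
#' adjustContrast(m)
#' @export
adjustContrast <- function(img, lowTail = 0.01, highTail = 0.99) {
  assertGray(img)
  if (!(lowTail >= 0 && lowTail < highTail && highTail <= 1))
    stop("need 0 <= lowTail < highTail <= 1")
  q <- quantile(img, c(lowTail, highTail), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: contrast adjustment skipped")
    return(img)
  }
  clip01((img - q[1]) / (q[2] - q[1]))
}

# Catmull-Rom cubic kernel (Keys, a = -0.5); weights at the 4 nearest
# sample points sum to 1, so constants are preserved exactly and an
# integer-aligned map is the identity.
cubicKernel <- function(x) {
  x <- abs(x)
  ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

# dense (nOut x nIn) separable bicubic interpolation matrix with
# pixel-centre alignment and edge replication
resampleMatrix <- function(nIn, nOut) {
  scale <- nIn / nOut
  src <- (seq_len(nOut) - 0.5) * scale - 0.5   # 0-based source coordinate
  base <- floor(src)
  M <- matrix(0, nOut, nIn)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 0), nIn - 1)     # replicate edges
    w <- cubicKernel(src - (base + k))
    M[cbind(seq_len(nOut), idx + 1)] <- M[cbind(seq_len(nOut), idx + 1)] + w
  }
  M / rowSums(M)
}

#' Resize a grayscale image to a square
#'
#' Bicubic (Catmull-Rom) resampling to `side x side` pixels with
#' pixel-centre alignment and replicated edges; the result is clipped
#' back to [0,1] (cubic kernels can overshoot).  Resizing to the input
#' size is the identity.
#'
#' @param img numeric matrix with values in [0,1].
#' @param side output side length in pixels (default 255).
#' @return `side x side` numeric matrix in [0,1].
#' @examples
#' resizeSquare(matrix(runif(100), 10), side = 5)
#' @export
resizeSquare <- function(img, side = 255L) {
  assertGray(img)
  side <- as.integer(side)
  if (side < 1L) stop("'side' must be >= 1")
  Mr <- resampleMatrix(nrow(img), side)
  Mc <- resampleMatrix(ncol(img), side)
  clip01(Mr %*% img %*% t(Mc))
}

#' Full fundus pre-processing pipeline
#'
#' The four pre-processing steps applied to a raw fundus photograph:
#' read as an RGB array, convert to grayscale, stretch contrast, and
#' resize to a `side x side` (default 255 x 255) grid.  Deterministic:
#' identical input arrays give identical outputs.
#'
#' @param img RGB array (`h x w x 3`), grayscale matrix, or
#'   single-channel array; values in [0,1] or [0,255].
#' @param side output side length (default 255).
#' @param lowTail,highTail contrast saturation fractions, see
#'   [adjustContrast()].
#' @return `side x side` numeric matrix with values in [0,1].
#' @examples
#' img <- makeFundusImage(grade = 3, seed = 1, side = 64)
#' pre <- preprocessFundus(img, side = 32)
#' dim(pre)
#' @export
preprocessFundus <- function(img, side = 255L, lowTail = 0.01,
                             highTail = 0.99) {
  resizeSquare(adjustContrast(toGrayscale(img), lowTail, highTail), side)
}
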