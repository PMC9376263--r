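# lesion intensity rates per severity grade 1..5 (expected counts):
# dark microaneurysm-like dots and bright exudate-like blobs; grade 1
# (no disease) has none, and rates increase with grade
lesionRates <- function() {
  list(dark = c(0, 4, 10, 20, 35),
       bright = c(0, 2, 6, 12, 20))
}

# draw a filled disc into img (matrix), returning the modified matrix
drawDisc <- function(img, cy, cx, r, value, blend = "set") {
  nr <- nrow(img); nc <- ncol(img)
  rows <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(img)
  d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  mask <- d2 <= r^2
  block <- img[rows, cols, drop = FALSE]
  block[mask] <- if (blend == "max") pmax(block[mask], value) else value
  img[rows, cols] <- block
  img
}

#' Generate one synthetic fundus-like image
#'
#' Draws a stylised retinal photograph: a circular field of view on a
#' dark background, a smooth radial intensity falloff, a bright optic
#' disc, dark random-walk vessels radiating from the disc, and
#' grade-dependent lesions -- small dark dots (microaneurysm-like) and
#' larger bright blobs (exudate-like) with Poisson counts whose rates
#' increase with severity grade; grade 1 has none.  Lesions are a
#' crude but controllable class signal, not clinical realism.  The
#' result is an RGB array with a reddish fundus tint; the number of
#' lesion pixels drawn is attached as attribute `lesionPixels` and the
#' grade as `grade`.  Fully reproducible per seed.
#'
#' @param grade severity grade 1..5 (1 = no disease, 5 =
#'   proliferative).
#' @param seed integer RNG seed.
#' @param side image side in pixels (default 510, so that resizing to
#'   255 is exercised).
#' @param vesselCount number of vessel walks (default 8).
#' @param discRadius optic-disc radius in pixels (default `side/10`).
#' @return `side x side x 3` numeric array in [0,1].
#' @examples
#' img <- makeFundusImage(grade = 4, seed = 1, side = 128)
#' attr(img, "lesionPixels")
#' @export
makeFundusImage <- function(grade, seed, side = 510L, vesselCount = 8L,
                            discRadius = side / 10) {
  grade <- as.integer(grade)
  if (grade < 1L || grade > 5L) stop("'grade' must be in 1..5")
  side <- as.integer(side)
  rates <- lesionRates()
  withr::with_seed(as.integer(seed), {
    ctr <- (side + 1) / 2
    fovR <- 0.48 * side
    d <- sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+"))
    fov <- d <= fovR
    # retina base: mid intensity with radial falloff plus mild texture
    img <- matrix(0.03, side, side)
    base <- 0.55 - 0.25 * (d / fovR)^2
    img[fov] <- base[fov] + rnorm(sum(fov), sd = 0.02)

    # optic disc: bright circle off-centre on a random side
    ang <- runif(1, -pi / 6, pi / 6) + sample(c(0, pi), 1)
    dcy <- ctr + 0.55 * fovR * sin(ang)
    dcx <- ctr + 0.55 * fovR * cos(ang)
    img <- drawDisc(img, dcy, dcx, discRadius, 0.92, blend = "max")

    # vessels: dark random walks out of the disc
    for (v in seq_len(vesselCount)) {
      theta <- runif(1, 0, 2 * pi)
      y <- dcy; x <- dcx
      nSteps <- round(1.2 * fovR)
      for (s in seq_len(nSteps)) {
        theta <- theta + rnorm(1, sd = 0.15)
        y <- y + sin(theta); x <- x + cos(theta)
        if ((y - ctr)^2 + (x - ctr)^2 > fovR^2) break
        img <- drawDisc(img, y, x, 1.6, 0.18)
      }
    }

    # grade-dependent lesions inside the field of view
    lesionPixels <- 0L
    placeLesions <- function(img, count, radiusRange, value) {
      for (i in seq_len(count)) {
        repeat {
          ly <- runif(1, ctr - fovR, ctr + fovR)
          lx <- runif(1, ctr - fovR, ctr + fovR)
          if ((ly - ctr)^2 + (lx - ctr)^2 <= (0.9 * fovR)^2) break
        }
        r <- runif(1, radiusRange[1], radiusRange[2])
        lesionPixels <<- lesionPixels + sum(
          outer((seq_len(side) - ly)^2, (seq_len(side) - lx)^2, "+") <= r^2)
        img <- drawDisc(img, ly, lx, r, value)
      }
      img
    }
    nDark <- rpois(1, rates$dark[grade])
    nBright <- rpois(1, rates$bright[grade])
    img <- placeLesions(img, nDark, c(1.5, 3) * side / 255, 0.08)
    img <- placeLesions(img, nBright, c(3, 6) * side / 255, 0.95)

    img <- clip01(img)
    out <- array(0, dim = c(side, side, 3))
    out[, , 1] <- img
    out[, , 2] <- img * 0.62
    out[, , 3] <- img * 0.28
    attr(out, "lesionPixels") <- lesionPixels
    attr(out, "grade") <- grade
    out
  })
}

#' Generate a balanced labelled synthetic image dataset
#'
#' `nPerClass` images per severity grade 1..5 (so `nPerClass = 190`
#' mirrors a balanced 950-image dataset).  Each image gets its own
#' seed derived from `seed`, keeping the whole set reproducible.
#'
#' @param nPerClass images per grade.
#' @param side image side in pixels (default 510).
#' @param seed integer base seed.
#' @return list with `images` (list of RGB arrays) and `labels`
#'   (integer grades 1..5).
#' @examples
#' d <- makeImageDataset(nPerClass = 1, side = 64, seed = 1)
#' table(d$labels)
#' @export
makeImageDataset <- function(nPerClass, side = 510L, seed = 1L) {
  if (nPerClass < 1L) stop("'nPerClass' must be >= 1")
  grades <- rep(1:5, each = nPerClass)
  images <- lapply(seq_along(grades), function(i)
    makeFundusImage(grades[i], seed = as.integer(seed) + i, side = side))
  list(images = images, labels = grades)
}

#' Generate a Gaussian feature table with controlled class separation
#'
#' Samples class `c` from an isotropic Gaussian (unit within-class
#' standard deviation) centred at a class-specific mean; the means sit
#' at the vertices of a regular simplex scaled so every pairwise
#' mean distance equals `separation` (in units of the within-class
#' standard deviation).  `separation = 0` collapses all classes onto
#' one distribution; large values make them trivially separable.
#'
#' @param nPerClass samples per class.
#' @param nClasses number of classes (default 5).
#' @param nFeatures feature dimensionality (default 10); must be at
#'   least `nClasses` so the equidistant mean arrangement fits.
#' @param separation pairwise mean distance in within-class SD units
#'   (default 3, a moderate overlap).
#' @param seed integer RNG seed.
#' @return list with `X` (matrix, rows shuffled across classes) and
#'   `y` (integer labels 1..nClasses).
#' @examples
#' d <- makeFeatureDataset(nPerClass = 20, seed = 1)
#' dim(d$X); table(d$y)
#' @export
makeFeatureDataset <- function(nPerClass, nClasses = 5L, nFeatures = 10L,
                               separation = 3, seed = 1L) {
  if (nPerClass < 1L) stop("'nPerClass' must be >= 1")
  if (separation < 0) stop("'separation' must be non-negative")
  if (nFeatures < nClasses)
    stop("'nFeatures' must be at least nClasses")
  withr::with_seed(as.integer(seed), {
    # class means at scaled unit vectors: every pair of distinct means
    # is separated by exactly 'separation'
    means <- matrix(0, nClasses, nFeatures)
    means[, seq_len(nClasses)] <- diag(nClasses) * (separation / sqrt(2))
    y <- rep(seq_len(nClasses), each = nPerClass)
    X <- means[y, , drop = FALSE] +
      matrix(rnorm(length(y) * nFeatures), ncol = nFeatures)
    ord <- sample(length(y))
    list(X = X[ord, , drop = FALSE], y = y[ord])
  })
}
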