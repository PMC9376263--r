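#' @import methods
#' @importFrom stats quantile rnorm runif rpois cov
NULL

# logistic sigmoid, numerically safe for large |z|
sigmoid <- function(z) 1 / (1 + exp(-z))

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the
#' convention used for the reported percentages), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(c(0.125, -0.125), 2)
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# validate a grayscale image: numeric matrix with values in [0,1]
assertGray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (anyNA(img) || min(img) < -1e-12 || max(img) > 1 + 1e-12)
    stop(sprintf("'%s' must contain finite values in [0,1]", arg),
         call. = FALSE)
  invisible(img)
}
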