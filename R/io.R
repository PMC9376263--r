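#' Read a fundus image from a PNG file
#'
#' Thin wrapper over \pkg{png} returning the `h x w x 3` array the
#' pre-processing pipeline expects (grayscale PNGs come back as a
#' matrix; alpha channels are dropped).
#'
#' @param path PNG file path.
#' @return numeric array or matrix with values in [0,1].
#' @export
readFundusPNG <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required to read PNG files")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3]
  if (length(dim(img)) == 3L && dim(img)[3L] == 2L)
    img <- img[, , 1L]
  img
}

#' Write a grayscale or RGB image to PNG
#'
#' @param img numeric matrix or `h x w x 3` array in [0,1].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFundusPNG <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required to write PNG files")
  a <- attributes(img)
  attributes(img) <- a[names(a) == "dim"]
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' Write / read a labelled feature matrix as CSV
#'
#' Plain-text container used by the command-line tools: a `label`
#' column followed by feature columns `f1..fn`, with the provenance
#' stage (e.g. "HOG" or "HOG-PCA") recorded in a `# stage:` comment on
#' the first line.
#'
#' @param X numeric feature matrix.
#' @param y integer labels (optional; zeros written when absent).
#' @param path CSV path.
#' @param stage provenance tag (default "HOG").
#' @return `path` (write) or a list with `X`, `y`, `stage` (read).
#' @export
writeFeatureCSV <- function(X, y = NULL, path, stage = "HOG") {
  X <- as.matrix(X)
  if (is.null(y)) y <- integer(nrow(X))
  df <- data.frame(label = as.integer(y), X)
  names(df) <- c("label", paste0("f", seq_len(ncol(X))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s rows: %d cols: %d", stage, nrow(X),
                     ncol(X)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  header <- readLines(path, n = 1L)
  stage <- if (startsWith(header, "# stage:"))
    strsplit(trimws(sub("^# stage:", "", header)), " ")[[1]][1]
  else "unknown"
  df <- utils::read.csv(path, comment.char = "#")
  list(X = as.matrix(df[, -1, drop = FALSE]), y = as.integer(df$label),
       stage = stage)
}
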