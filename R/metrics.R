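metricNames <- c("accuracy", "precision", "recall", "specificity",
                 "mcc", "f_measure", "g_mean")

# the seven measures from tp/fp/fn/tn, as fractions (MCC in [-1,1]);
# zero denominators yield NA with a warning, never a silent 0
computeMetrics <- function(tp, fp, fn, tn, accuracy = NULL) {
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  total <- tp + fp + fn + tn
  if (is.null(accuracy)) accuracy <- safeDiv(tp + tn, total, "accuracy")
  precision <- safeDiv(tp, tp + fp, "precision")
  recall <- safeDiv(tp, tp + fn, "recall")
  specificity <- safeDiv(tn, tn + fp, "specificity")
  fMeasure <- if (isTRUE(precision + recall > 0))
    2 * precision * recall / (precision + recall)
  else {
    warning("F-measure undefined (precision + recall is zero)",
            call. = FALSE)
    NA_real_
  }
  gMean <- sqrt(recall * precision)
  mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- safeDiv(tp * tn - fp * fn, mccDen, "MCC")
  c(accuracy = accuracy, precision = precision, recall = recall,
    specificity = specificity, mcc = mcc, f_measure = fMeasure,
    g_mean = gMean)
}

#' Binary classification metrics from confusion counts
#'
#' The seven measures computed from true/false positive/negative
#' counts: accuracy (tp+tn)/total, precision tp/(tp+fp), recall
#' tp/(tp+fn), specificity tn/(tn+fp), Matthews correlation
#' coefficient, F-measure (harmonic mean of precision and recall) and
#' G-mean, here the geometric mean of recall and precision.  A zero
#' denominator makes the affected metric NA with a warning.
#'
#' @param tp,fp,fn,tn non-negative confusion counts.
#' @return an [EvalReport-class]; see [metricsTable()] for the
#'   percentage table.
#' @examples
#' metricsTable(binaryMetrics(tp = 151, fp = 1, fn = 0, tn = 38))
#' @export
binaryMetrics <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  new("EvalReport", counts = counts,
      metrics = computeMetrics(tp, fp, fn, tn),
      mode = "binary", nClasses = 2L)
}

#' One-vs-rest confusion counts per class
#'
#' Reduces a K x K confusion matrix (rows = truth, columns =
#' prediction) to K binary problems: for class c, `tp = M[c,c]`,
#' `fn = rowSum - tp`, `fp = colSum - tp`, `tn = total - tp - fp - fn`.
#'
#' @param M square non-negative confusion matrix.
#' @return data.frame with columns class, tp, fp, fn, tn.
#' @examples
#' ovrCounts(diag(c(3, 4, 5)))
#' @export
ovrCounts <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("'M' must be square")
  if (any(M < 0)) stop("'M' must be non-negative")
  tp <- diag(M)
  fn <- rowSums(M) - tp
  fp <- colSums(M) - tp
  tn <- sum(M) - tp - fp - fn
  data.frame(class = seq_len(nrow(M)), tp = tp, fp = fp, fn = fn, tn = tn,
             row.names = NULL)
}

#' Multi-class metrics by one-vs-rest micro-aggregation
#'
#' Reduces the K x K confusion matrix to per-class one-vs-rest counts
#' ([ovrCounts()]), sums them (micro-averaging), and applies the
#' binary formulae for precision, recall, specificity, MCC, F-measure
#' and G-mean to the summed counts.  Accuracy is the class-averaged
#' one-vs-rest accuracy, which for n observations and e total
#' misclassifications equals `(K n - 2 e) / (K n)`.
#'
#' @param M square confusion matrix (rows = truth, columns =
#'   prediction), K >= 3.
#' @return an [EvalReport-class].
#' @examples
#' M <- matrix(0, 5, 5); diag(M) <- 38
#' M[1, 2] <- 2; diag(M)[1] <- 36
#' metricsTable(multiclassMetrics(M))
#' @export
multiclassMetrics <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("'M' must be square")
  if (nrow(M) < 3L)
    stop("multi-class aggregation needs K >= 3; use binaryMetrics()")
  ovr <- ovrCounts(M)
  perClassAcc <- (ovr$tp + ovr$tn) / (ovr$tp + ovr$fp + ovr$fn + ovr$tn)
  counts <- c(tp = sum(ovr$tp), fp = sum(ovr$fp), fn = sum(ovr$fn),
              tn = sum(ovr$tn))
  new("EvalReport", counts = counts,
      metrics = computeMetrics(unname(counts["tp"]), unname(counts["fp"]),
                               unname(counts["fn"]), unname(counts["tn"]),
                               accuracy = mean(perClassAcc)),
      mode = "multiclass", nClasses = nrow(M))
}

#' Confusion matrix from truth and predictions
#'
#' @param truth,pred integer labels in 1..nClasses.
#' @param nClasses number of classes (default `max(truth, pred)`).
#' @return nClasses x nClasses integer matrix, rows = truth.
#' @examples
#' confusionMatrix(c(1, 1, 2), c(1, 2, 2), nClasses = 2)
#' @export
confusionMatrix <- function(truth, pred, nClasses = max(truth, pred)) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred))
    stop("'truth' and 'pred' must have the same length")
  if (any(c(truth, pred) < 1L) || any(c(truth, pred) > nClasses))
    stop("labels must lie in 1..nClasses")
  as.matrix(table(factor(truth, levels = seq_len(nClasses)),
                  factor(pred, levels = seq_len(nClasses))))
}

#' Evaluate predictions in binary or multi-class mode
#'
#' @param truth,pred integer labels.
#' @param mode `"binary"` (labels 1 = negative, 2 = positive) or
#'   `"multiclass"`.
#' @param nClasses number of classes.
#' @return an [EvalReport-class].
#' @examples
#' evaluatePredictions(c(1, 2, 2), c(1, 2, 1), mode = "binary")
#' @export
evaluatePredictions <- function(truth, pred,
                                mode = c("multiclass", "binary"),
                                nClasses = max(truth, pred)) {
  mode <- match.arg(mode)
  M <- confusionMatrix(truth, pred, nClasses)
  if (mode == "binary") {
    if (nrow(M) != 2L) stop("binary mode needs labels in 1..2")
    # class 2 (disease) is the positive class
    binaryMetrics(tp = M[2, 2], fp = M[1, 2], fn = M[2, 1], tn = M[1, 1])
  } else {
    multiclassMetrics(M)
  }
}

#' Report metrics as percentages
#'
#' @param object an [EvalReport-class].
#' @param digits decimals to keep (default 2), rounded half away from
#'   zero as in the reported tables.
#' @param ... unused.
#' @return one-row data.frame of percentages (MCC in [-100, 100]).
#' @rdname metricsTable
#' @export
setMethod("metricsTable", "EvalReport", function(object, digits = 2, ...) {
  out <- as.data.frame(as.list(roundHalfUp(object@metrics * 100, digits)))
  names(out) <- metricNames
  out
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s, %d classes)\n", object@mode,
              object@nClasses))
  cat(sprintf("  counts: tp=%g fp=%g fn=%g tn=%g\n",
              object@counts["tp"], object@counts["fp"],
              object@counts["fn"], object@counts["tn"]))
  tab <- metricsTable(object)
  cat(paste(sprintf("%s=%.2f", names(tab), unlist(tab)),
            collapse = "  "), "\n")
})
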