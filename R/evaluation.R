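#' Threshold a probability into a stress class
#'
#' `high` if and only if the probability is greater than or equal to the
#' threshold (ties go to `high`, the clinically relevant minority class).
#'
#' @param prob Probabilities in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]`.
#' @return Factor with levels `low`, `high`.
#' @export
classify_stress <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  factor(ifelse(prob >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Build a confusion matrix (positive class = high stress)
#'
#' @param truth,prediction Vectors of `low`/`high` labels (factor or
#'   character), equal length.
#' @return Object of class `stress_confusion`: list with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(truth, prediction) {
  truth <- as.character(truth)
  prediction <- as.character(prediction)
  if (length(truth) != length(prediction) || length(truth) < 1L)
    stop("truth and prediction must have equal positive length", call. = FALSE)
  if (!all(c(truth, prediction) %in% c("low", "high")))
    stop("labels must be 'low' or 'high'", call. = FALSE)
  structure(list(
    tp = sum(truth == "high" & prediction == "high"),
    fp = sum(truth == "low" & prediction == "high"),
    fn = sum(truth == "high" & prediction == "low"),
    tn = sum(truth == "low" & prediction == "low")),
    class = "stress_confusion")
}

#' Confusion matrix from raw counts
#'
#' @param tp,fp,fn,tn Nonnegative integer counts; their total must be
#'   positive.
#' @return Object of class `stress_confusion`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be nonnegative", call. = FALSE)
  if (sum(counts) <= 0)
    stop("confusion matrix total must be positive", call. = FALSE)
  structure(as.list(counts), class = "stress_confusion")
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Applies the four standard formulas exactly. When a denominator is zero
#' the metric is reported as `NA` (undefined) with a warning rather than
#' silently coerced to 0.
#'
#' @param cm A `stress_confusion` object.
#' @return Object of class `stress_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (fractions in `[0, 1]` or `NA`).
#' @examples
#' classification_metrics(confusion_matrix(926, 76, 142, 212))
#' @export
classification_metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total <= 0) stop("confusion matrix total must be positive",
                       call. = FALSE)
  accuracy <- (cm$tp + cm$tn) / total
  precision <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else {
    warning("precision undefined: no predicted positives", call. = FALSE)
    NA_real_
  }
  recall <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else {
    warning("recall undefined: no true positives in the sample",
            call. = FALSE)
    NA_real_
  }
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
  else if (precision + recall > 0) 2 * precision * recall /
    (precision + recall)
  else {
    warning("F1 undefined: precision + recall = 0", call. = FALSE)
    NA_real_
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1), class = "stress_metrics")
}

#' @export
print.stress_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("high", "low"),
                              predicted = c("high", "low")))
  cat("Confusion matrix (positive class = high stress):\n")
  print(m)
  invisible(x)
}

#' @export
print.stress_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else
    sprintf("%.2f%%", 100 * v)
  cat("accuracy: ", pct(x$accuracy), "\nprecision:", pct(x$precision),
      "\nrecall:   ", pct(x$recall), "\nF1:       ", pct(x$f1), "\n")
  invisible(x)
}

#' Published benchmark confusion-matrix counts
#'
#' Confusion-matrix counts (positive class = high stress) reported in the
#' stress-classification literature for six classifiers evaluated on the
#' KNHANES VI survey test set, shipped as a plain-text fixture. Metrics
#' recomputed from these counts with [classification_metrics()] make the
#' formula identities checkable; note that for several rows they do not
#' match the headline percentages quoted alongside them in the source,
#' an inconsistency this package surfaces rather than resolves.
#'
#' @return Tibble with columns `model`, `tp`, `fp`, `fn`, `tn`.
#' @export
benchmark_confusions <- function() {
  path <- system.file("extdata", "benchmark_confusions.tsv", package = "elstm",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
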