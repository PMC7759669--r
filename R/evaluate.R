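# Evaluation: accuracy, confusion matrices, per-subject report tables.

#' Classification accuracy (percent)
#'
#' 100 * (number correct) / n. For the four-class task this is the headline
#' fraction-correct metric; the binary one-vs-rest reading
#' (TP+TN)/(TP+TN+FP+FN) per class is available via
#' \code{\link{oneVsRestStats}}.
#'
#' @param trueLabels,predictedLabels equal-length vectors (factor/character/integer).
#' @return Accuracy in percent.
#' @export
accuracy <- function(trueLabels, predictedLabels) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors differ in length")
  if (length(trueLabels) == 0) stop("empty label vectors")
  100 * mean(as.character(trueLabels) == as.character(predictedLabels))
}

#' Confusion matrix
#'
#' counts[i, j] = number of trials with true class i predicted as class j.
#'
#' @param trueLabels,predictedLabels equal-length label vectors.
#' @param classes class levels in order; defaults to the union of observed
#'   levels.
#' @return Integer matrix with classes as dimnames (rows = true).
#' @export
confusionCounts <- function(trueLabels, predictedLabels, classes = NULL) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors differ in length")
  tl <- as.character(trueLabels); pl <- as.character(predictedLabels)
  if (is.null(classes)) {
    classes <- if (is.factor(trueLabels)) levels(trueLabels) else sort(unique(c(tl, pl)))
  }
  if (!all(tl %in% classes) || !all(pl %in% classes))
    stop("labels outside the declared classes")
  tab <- table(factor(tl, levels = classes), factor(pl, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' One-vs-rest TP/FP/FN/TN per class
#'
#' @param cm confusion matrix from \code{\link{confusionCounts}}.
#' @return data.frame with one row per class and the binary accuracy
#'   (TP+TN)/(TP+TN+FP+FN) of each one-vs-rest problem.
#' @export
oneVsRestStats <- function(cm) {
  n <- sum(cm)
  out <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    data.frame(class = rownames(cm)[i], TP = tp, FP = fp, FN = fn, TN = tn,
               binaryAccuracy = 100 * (tp + tn) / n)
  })
  do.call(rbind, out)
}

#' Per-subject accuracy report
#'
#' @param accuracies named numeric vector of per-subject accuracies (percent).
#' @return data.frame with one row per subject plus a final AVG row holding
#'   the arithmetic mean.
#' @export
subjectReport <- function(accuracies) {
  stopifnot(length(accuracies) >= 1)
  if (is.null(names(accuracies)))
    names(accuracies) <- as.character(seq_along(accuracies))
  data.frame(subject = c(names(accuracies), "AVG"),
             accuracy = c(unname(accuracies), mean(accuracies)))
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report data.frame (e.g. from \code{\link{subjectReport}}).
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return Invisibly, the two file paths.
#' @export
writeReport <- function(report, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  write.csv(report, csv, row.names = FALSE)
  jsonlite::write_json(report, js, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
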