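# Confusion matrices, per-class precision/recall/F1 and support-weighted or
# macro F-measure. The weighted F-measure is the headline metric for the
# class-imbalanced pan-cancer problem.

#' Confusion matrix over a fixed label order
#'
#' Entry (i, j) counts samples of true class i predicted as class j. The
#' label order fixes both dimensions, so rows/columns line up across
#' reports even for classes with no samples.
#'
#' @param true_labels,pred_labels Character or factor vectors of equal
#'   length.
#' @param label_order Character vector of all class labels; defaults to
#'   [class_vocabulary()].
#' @return Integer matrix with `label_order` dimnames (rows = true).
#' @export
confusion_matrix <- function(true_labels, pred_labels,
                             label_order = class_vocabulary()) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  stopifnot(length(true_labels) == length(pred_labels))
  unknown <- setdiff(unique(c(true_labels, pred_labels)), label_order)
  if (length(unknown) > 0) {
    stop("label(s) outside the vocabulary: ", paste(unknown, collapse = ", "))
  }
  tf <- factor(true_labels, levels = label_order)
  pf <- factor(pred_labels, levels = label_order)
  m <- table(tf, pf)
  cm <- matrix(as.integer(m), nrow(m), ncol(m),
               dimnames = list(label_order, label_order))
  cm
}

#' Per-class precision, recall and F1
#'
#' From a square confusion matrix: `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `F1 = 2PR / (P + R)`. Whenever a denominator
#' vanishes the metric is 0 and the class is flagged, matching the common
#' zero-division convention of standard metric libraries.
#'
#' @param confusion Square non-negative integer matrix (rows = true).
#' @return Data frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support` and `zero_division` (logical flag).
#' @export
per_class_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(confusion >= 0))
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  data.frame(
    class = rownames(confusion) %||% as.character(seq_len(nrow(confusion))),
    precision = precision, recall = recall, f1 = f1,
    support = as.integer(support),
    zero_division = predicted == 0 | support == 0 | pr == 0,
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-class F1 scores
#'
#' `weighted` is the support-weighted mean of per-class F1 (weights
#' proportional to the number of true instances), the metric of record
#' under large class imbalance; `macro` is the plain (unweighted) mean.
#'
#' @param f1 Numeric vector of per-class F1 scores.
#' @param support Integer vector of true-instance counts, same length.
#' @param mode `"weighted"` or `"macro"`.
#' @return A single number in \[0, 1\].
#' @export
aggregate_f <- function(f1, support, mode = c("weighted", "macro")) {
  mode <- match.arg(mode)
  stopifnot(length(f1) == length(support))
  if (mode == "weighted") {
    if (sum(support) == 0) stop("total support is zero; nothing to weight")
    sum(support * f1) / sum(support)
  } else {
    mean(f1)
  }
}

#' Misclassification profile of one class
#'
#' Off-diagonal rates of a confusion-matrix row, normalised by the class
#' support and ranked in descending order — where do this class's errors
#' go? The rates sum to `1 - recall`.
#'
#' @param confusion Square confusion matrix with dimnames.
#' @param class Class label (row) to profile.
#' @return Data frame with columns `predicted_class` and `rate`, nonzero
#'   rates only, descending.
#' @export
misclassification_profile <- function(confusion, class) {
  if (!class %in% rownames(confusion)) {
    stop("class not in confusion matrix: ", class)
  }
  row <- confusion[class, ]
  support <- sum(row)
  others <- setdiff(names(row), class)
  rate <- if (support > 0) row[others] / support else
    stats::setNames(rep(0, length(others)), others)
  keep <- rate > 0
  out <- data.frame(predicted_class = others[keep],
                    rate = unname(rate[keep]), row.names = NULL)
  out[order(-out$rate), , drop = FALSE]
}

#' Full classification report
#'
#' Bundles the confusion matrix, per-class metrics and both aggregate
#' F-measures into one object.
#'
#' @param true_labels,pred_labels Label vectors of equal length.
#' @param label_order Class order; defaults to [class_vocabulary()].
#' @return An object of class `classification_report`: list with
#'   `confusion`, `per_class`, `weighted_f`, `macro_f`, `accuracy` and
#'   `n`.
#' @export
classification_report <- function(true_labels, pred_labels,
                                  label_order = class_vocabulary()) {
  cm <- confusion_matrix(true_labels, pred_labels, label_order)
  pc <- per_class_metrics(cm)
  structure(list(
    confusion = cm,
    per_class = pc,
    weighted_f = aggregate_f(pc$f1, pc$support, "weighted"),
    macro_f = aggregate_f(pc$f1, pc$support, "macro"),
    accuracy = sum(diag(cm)) / sum(cm),
    n = sum(cm)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 4, ...) {
  cat("Classification report (", x$n, " samples)\n", sep = "")
  cat("  accuracy:   ", round(x$accuracy, digits), "\n", sep = "")
  cat("  weighted F: ", round(x$weighted_f, digits), "\n", sep = "")
  cat("  macro F:    ", round(x$macro_f, digits), "\n", sep = "")
  present <- x$per_class[x$per_class$support > 0, ]
  print(format(present, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a classification report to disk
#'
#' Emits `confusion.tsv` and `per_class.tsv` (human-readable tables) plus
#' `summary.json` (aggregates) into a directory.
#'
#' @param report A `classification_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$confusion, file.path(dir, "confusion.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(report$per_class, file.path(dir, "per_class.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = report$accuracy, weighted_f = report$weighted_f,
         macro_f = report$macro_f, n = report$n),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
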