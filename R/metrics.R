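#' Micro-averaged confusion counts
#'
#' Sums one-vs-rest TP/TN/FP/FN over all classes. For a two-class task this
#' convention forces TP = TN and FP = FN, which is why the reported
#' accuracy, precision, recall, specificity, F1 and NPV coincide in binary
#' micro-averaged reports.
#'
#' @param true_labels,predicted_labels Equal-length vectors of class labels.
#' @param classes Optional vector fixing the class set (defaults to the
#'   union of observed labels).
#' @return A list of class \code{confusion_counts} with integer fields
#'   \code{tp}, \code{tn}, \code{fp}, \code{fn}.
#' @export
micro_confusion <- function(true_labels, predicted_labels, classes = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("contract violation: label vectors must have equal length")
  if (is.null(classes))
    classes <- sort(unique(c(as.character(true_labels),
                             as.character(predicted_labels))))
  tp <- tn <- fp <- fn <- 0L
  for (cls in classes) {
    pos_true <- true_labels == cls
    pos_pred <- predicted_labels == cls
    tp <- tp + sum(pos_true & pos_pred)
    tn <- tn + sum(!pos_true & !pos_pred)
    fp <- fp + sum(!pos_true & pos_pred)
    fn <- fn + sum(pos_true & !pos_pred)
  }
  confusion_counts(tp, tn, fp, fn)
}

#' @rdname micro_confusion
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Confusion-count metric suite
#'
#' Computes the count-based members of the twelve-metric report, each as an
#' exact (unrounded) percentage:
#' accuracy \code{(TP+TN)/(TP+TN+FP+FN)}, precision \code{TP/(TP+FP)},
#' specificity \code{TN/(TN+FP)}, recall = sensitivity \code{TP/(TP+FN)},
#' Dice \code{2TP/(2TP+FP+FN)}, F1 (harmonic mean of precision and recall),
#' Youden index (specificity + sensitivity - 100), NPV \code{TN/(TN+FN)},
#' and IoU \code{TP/(TP+FP+FN)}. A zero denominator yields \code{NA} for
#' that metric rather than an error. AUC and cosine similarity need
#' per-sample scores and are merged separately (see
#' \code{\link{auc_rank}}, \code{\link{cosine_similarity}} and
#' \code{\link{metric_report}}).
#'
#' @param counts A \code{\link{confusion_counts}} object.
#' @return Named list of percentages (class \code{metric_report}, with
#'   \code{auc} and \code{cosine_similarity} set to \code{NA}).
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + tn + fp + fn == 0) stop("contract violation: all counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  specificity <- ratio(tn, tn + fp)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  metric_report(
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    f1 = f1,
    precision = precision,
    recall = recall,
    specificity = specificity,
    auc = NA_real_,
    sensitivity = recall,
    iou = ratio(tp, tp + fp + fn),
    dice = ratio(2 * tp, 2 * tp + fp + fn),
    cosine_similarity = NA_real_,
    youden_index = if (is.na(specificity) || is.na(recall)) NA_real_
                   else specificity + recall - 100,
    npv = ratio(tn, tn + fn))
}

#' Assemble a metric report
#'
#' @param accuracy,f1,precision,recall,specificity,auc,sensitivity,iou,dice,cosine_similarity,youden_index,npv
#'   Percentages (Youden may be negative).
#' @return A named list of class \code{metric_report}.
#' @export
metric_report <- function(accuracy, f1, precision, recall, specificity, auc,
                          sensitivity, iou, dice, cosine_similarity,
                          youden_index, npv) {
  structure(list(accuracy = accuracy, f1 = f1, precision = precision,
                 recall = recall, specificity = specificity, auc = auc,
                 sensitivity = sensitivity, iou = iou, dice = dice,
                 cosine_similarity = cosine_similarity,
                 youden_index = youden_index, npv = npv),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> (%)\n")
  for (m in names(x))
    cat(sprintf("  %-18s %s\n", m,
                if (is.na(x[[m]])) "NA" else sprintf("%.2f", x[[m]])))
  invisible(x)
}

#' Round half-up for display
#'
#' Table-style presentation rounding (0.005 rounds up), applied only when
#' formatting; all internal arithmetic stays unrounded.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve via the Mann-Whitney rank-sum statistic, with
#' tied scores counted one half, expressed as a percentage.
#'
#' @param true_labels Binary truth; the larger (last in sort order) level or
#'   value 1/TRUE is the positive class.
#' @param scores Numeric scores, higher = more positive.
#' @param positive Optional explicit positive label.
#' @return AUC percentage.
#' @export
auc_rank <- function(true_labels, scores, positive = NULL) {
  if (is.null(positive)) {
    lv <- sort(unique(as.character(true_labels)))
    if (length(lv) != 2L) stop("undefined AUC: need exactly two classes")
    positive <- lv[2]
  }
  pos <- as.character(true_labels) == as.character(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("undefined AUC: both classes must be present")
  r <- rank(scores)  # average ranks handle ties at 1/2
  100 * (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean cosine similarity between truth and predicted probabilities
#'
#' Per-sample cosine between the one-hot truth row and the predicted
#' probability row, averaged and expressed as a percentage. Uniform binary
#' predictions score \code{100/sqrt(2)} (70.71\%) against any one-hot truth.
#'
#' @param one_hot_truth n x K 0/1 matrix, one 1 per row.
#' @param predicted_probabilities n x K matrix, rows approximately summing
#'   to one.
#' @return Percentage.
#' @export
cosine_similarity <- function(one_hot_truth, predicted_probabilities) {
  stopifnot(all(dim(one_hot_truth) == dim(predicted_probabilities)))
  tn <- sqrt(rowSums(one_hot_truth^2))
  pn <- sqrt(rowSums(predicted_probabilities^2))
  if (any(tn == 0) || any(pn == 0))
    stop("degenerate input: zero-norm row in cosine similarity")
  dots <- rowSums(one_hot_truth * predicted_probabilities)
  100 * mean(dots / (tn * pn))
}

#' Equal-weight combination of the twelve metrics
#'
#' The weighted sum used for overall optimizer/model comparison: the
#' arithmetic mean (weight 1/12 each) of accuracy, F1, precision, recall,
#' specificity, AUC, sensitivity, IoU, Dice, cosine similarity, Youden
#' index and NPV.
#'
#' @param report A complete \code{metric_report}.
#' @return Percentage.
#' @export
weighted_sum <- function(report) {
  vals <- unlist(report[c("accuracy", "f1", "precision", "recall",
                          "specificity", "auc", "sensitivity", "iou", "dice",
                          "cosine_similarity", "youden_index", "npv")])
  if (anyNA(vals)) stop("undefined weighted sum: report has undefined metrics")
  mean(vals)
}

#' Average metric reports across models
#'
#' Per-metric arithmetic mean over a list of reports (unrounded values;
#' round only for display).
#'
#' @param reports Non-empty list of \code{metric_report}s.
#' @return A \code{metric_report} of means (\code{NA} components propagate).
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) < 1L) stop("contract violation: no reports to aggregate")
  fields <- names(reports[[1]])
  means <- lapply(fields, function(f)
    mean(vapply(reports, function(r) r[[f]], numeric(1))))
  names(means) <- fields
  do.call(metric_report, means)
}

#' Write metric reports as a metrics-by-models table
#'
#' Emits the report in the study's table shape: metric names as rows and
#' one column per model/run, values rounded half-up to 2 decimals. Also
#' writable as JSON (unrounded).
#'
#' @param reports Named list of \code{metric_report}s (names become columns).
#' @param path Output path (.csv or .json decided by \code{format}).
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_report_table <- function(reports, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(lapply(reports, unclass_deep), path,
                         auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  fields <- names(reports[[1]])
  df <- data.frame(metric = fields)
  for (nm in names(reports))
    df[[nm]] <- vapply(fields, function(f)
      round_half_up(reports[[nm]][[f]]), numeric(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Reported confusion counts of the published study
#'
#' The per-model micro-averaged TP/TN/FP/FN counts and the printed
#' accuracy, AUC and Youden-index rows for the nine transfer-learning
#' models under each of the two metaheuristic optimizers, as published in
#' the study this package reimplements. These are inputs for golden
#' arithmetic tests and for aggregation; the package recomputes every
#' count-derived metric from the counts.
#'
#' @return A data frame with columns \code{optimizer}, \code{model},
#'   \code{tp}, \code{tn}, \code{fp}, \code{fn}, \code{accuracy_printed},
#'   \code{auc_printed}, \code{youden_printed}.
#' @export
published_results <- function() {
  models <- c("Xception", "VGG16", "VGG19", "MobileNet", "MobileNetV2",
              "MobileNetV3Small", "MobileNetV3Large", "NASNetMobile",
              "DenseNet201")
  ao <- data.frame(
    optimizer = "AO", model = models,
    tp = c(5351, 5357, 5341, 5356, 5333, 5329, 5299, 5311, 5359),
    fp = c(25, 35, 47, 20, 27, 47, 81, 65, 17),
    accuracy_printed = c(99.53, 99.35, 99.13, 99.63, 99.50, 99.13, 98.49,
                         98.79, 99.68),
    auc_printed = c(99.95, 99.98, 99.29, 99.95, 99.86, 99.90, 99.82, 99.20,
                    99.99),
    youden_printed = c(99.07, 98.70, 98.26, 99.26, 98.99, 98.25, 96.99,
                       97.58, 99.37))
  gto <- data.frame(
    optimizer = "GTO", model = models,
    tp = c(5356, 5320, 5258, 5342, 5200, 5232, 5230, 4779, 5334),
    fp = c(20, 48, 130, 22, 176, 148, 130, 617, 30),
    accuracy_printed = c(99.63, 99.11, 97.59, 99.59, 96.73, 97.25, 97.57,
                         88.57, 99.44),
    auc_printed = c(99.99, 99.97, 99.71, 99.99, 99.24, 99.64, 99.57, 94.99,
                    99.99),
    youden_printed = c(99.26, 98.21, 95.17, 99.18, 93.45, 94.50, 95.15,
                       77.13, 98.88))
  out <- rbind(ao, gto)
  out$tn <- out$tp  # binary micro-averaging: TP = TN, FP = FN
  out$fn <- out$fp
  out[, c("optimizer", "model", "tp", "tn", "fp", "fn",
          "accuracy_printed", "auc_printed", "youden_printed")]
}
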