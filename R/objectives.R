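# Class-weighted binary cross-entropy and the imbalance-aware metric suite
# (balanced accuracy, Matthews correlation, ROC AUC, precision-recall AUC).

#' Positive-class loss weight from the dataset's positive ratio
#'
#' `w = (1 - pos_ratio) / pos_ratio`, i.e. the negative:positive ratio of the
#' analyzed dataset, so that at 1:10 imbalance (`pos_ratio = 1/11`) each
#' positive weighs as much as ten negatives.
#'
#' @param pos_ratio Fraction of positives, strictly inside (0, 1).
#' @return The weight w.
#' @export
class_weight <- function(pos_ratio) {
  if (!is.numeric(pos_ratio) || pos_ratio <= 0 || pos_ratio >= 1) {
    stop("`pos_ratio` must lie strictly inside (0, 1)")
  }
  (1 - pos_ratio) / pos_ratio
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Weighted binary cross-entropy
#'
#' `J = -(1/N) * sum(w * y * log(p) + (1 - y) * log(1 - p))`: the weight
#' applies to the positive term only, which is what lets it counter class
#' imbalance (with `w = class_weight(pos_ratio)` the two classes contribute
#' equal expected gradient mass). `weight_both = TRUE` multiplies both terms
#' by w instead, turning w into a constant factor; it is kept only for
#' fidelity experiments. Probabilities are clamped to `[eps, 1 - eps]`.
#'
#' @param y Binary labels.
#' @param p Predicted probabilities in (0, 1).
#' @param w Positive-class weight.
#' @param weight_both Apply w to both terms.
#' @param eps Clamping epsilon.
#' @return Non-negative scalar loss.
#' @export
weighted_bce <- function(y, p, w = 1, weight_both = FALSE, eps = 1e-7) {
  if (length(y) == 0L) stop("empty score set")
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  p <- clamp_prob(p, eps)
  wn <- if (weight_both) w else 1
  -mean(w * y * log(p) + wn * (1 - y) * log(1 - p))
}

#' Confusion counts at a probability threshold
#'
#' A prediction is positive iff `p >= threshold` (ties count positive).
#'
#' @param y Binary labels.
#' @param p Predicted probabilities.
#' @param threshold Threshold in (0, 1), default 0.5.
#' @return List of class `confusion_counts` with TP, TN, FP, FN.
#' @export
confusion_counts <- function(y, p, threshold = 0.5) {
  stopifnot(length(y) == length(p), threshold > 0, threshold < 1)
  pred <- as.numeric(p >= threshold)
  structure(list(TP = sum(pred == 1 & y == 1), TN = sum(pred == 0 & y == 0),
                 FP = sum(pred == 1 & y == 0), FN = sum(pred == 0 & y == 1),
                 threshold = threshold),
            class = "confusion_counts")
}

#' Balanced accuracy
#'
#' `BACC = (TP/(TP+FN) + TN/(TN+FP)) / 2`. When one class is absent its term
#' is taken as 0 and a warning is raised.
#'
#' @param counts `confusion_counts` (or list with TP, TN, FP, FN).
#' @return Value in `[0, 1]`.
#' @export
bacc <- function(counts) {
  sens <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
          else { warning("no positives: sensitivity term set to 0"); 0 }
  spec <- if (counts$TN + counts$FP > 0) counts$TN / (counts$TN + counts$FP)
          else { warning("no negatives: specificity term set to 0"); 0 }
  (sens + spec) / 2
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; 0 when any
#' denominator factor is 0 (the correlation is undefined then, e.g. when all
#' predictions fall in one class).
#'
#' @param counts `confusion_counts` (or list with TP, TN, FP, FN).
#' @return Value in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability
#' `P(p_pos > p_neg) + 0.5 * P(p_pos == p_neg)` via midranks.
#'
#' @param y Binary labels (both classes must be present).
#' @param p Predicted probabilities or scores (any monotone scale).
#' @return Value in `[0, 1]`.
#' @export
roc_auc <- function(y, p) {
  stopifnot(length(y) == length(p))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("roc_auc requires both classes present")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: with items ranked by descending score, for
#' each distinct score threshold the prefix precision P_k and recall R_k are
#' evaluated and the area is `sum((R_k - R_{k-1}) * P_k)`. No trapezoidal
#' interpolation (which overestimates PR area).
#'
#' @param y Binary labels (at least one positive).
#' @param p Predicted probabilities or scores.
#' @return Value in `[0, 1]`.
#' @export
auprc <- function(y, p) {
  stopifnot(length(y) == length(p))
  n_pos <- sum(y == 1)
  if (n_pos == 0L) stop("auprc requires at least one positive")
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  cum_tp <- cumsum(ys)
  k <- seq_along(ys)
  last_of_score <- !duplicated(ps, fromLast = TRUE)   # prefix = all p >= s
  P <- (cum_tp / k)[last_of_score]
  R <- (cum_tp / n_pos)[last_of_score]
  sum((R - c(0, R[-length(R)])) * P)
}

#' Full metrics report for a labeled score set
#'
#' @param y Binary labels.
#' @param p Predicted probabilities.
#' @param threshold Threshold for the confusion counts.
#' @return List of class `metrics_report` with `bacc`, `mcc`, `auc`, `auprc`,
#'   `counts` and `threshold`.
#' @export
metrics_report <- function(y, p, threshold = 0.5) {
  counts <- confusion_counts(y, p, threshold)
  structure(list(bacc = bacc(counts), mcc = mcc(counts),
                 auc = roc_auc(y, p), auprc = auprc(y, p),
                 counts = counts, threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("BACC %.4f  MCC %.4f  AUC %.4f  AUPRC %.4f  (TP %d TN %d FP %d FN %d @ %.2f)\n",
              x$bacc, x$mcc, x$auc, x$auprc, x$counts$TP, x$counts$TN,
              x$counts$FP, x$counts$FN, x$threshold))
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param report `metrics_report`.
#' @param path Output path; `format` is JSON or a one-line TSV suited to
#'   aggregation across runs.
#' @param format `"json"` or `"tsv"`.
#' @export
write_metrics <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  flat <- list(bacc = report$bacc, mcc = report$mcc, auc = report$auc,
               auprc = report$auprc, TP = report$counts$TP,
               TN = report$counts$TN, FP = report$counts$FP,
               FN = report$counts$FN, threshold = report$threshold)
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(flat), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
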