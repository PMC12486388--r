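# Evaluation metrics: confusion counts, the five threshold metrics
# (ACC, Precision, Recall, F1, MCC) from their closed-form definitions,
# AUROC via the rank (Mann-Whitney) statistic with tie correction, and
# AUPRC as the step integral of the precision-recall curve.

#' Confusion counts at a threshold
#'
#' @param labels Binary 0/1 ground-truth labels.
#' @param calls Binary 0/1 predicted calls of the same length.
#' @return Object of class `ppis_confusion`: list with integers `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    stop("labels (", length(labels), ") and calls (", length(calls),
         ") differ in length")
  }
  labels <- as.integer(labels > 0); calls <- as.integer(calls > 0)
  structure(list(TP = sum(labels == 1 & calls == 1),
                 TN = sum(labels == 0 & calls == 0),
                 FP = sum(labels == 0 & calls == 1),
                 FN = sum(labels == 1 & calls == 0)),
            class = "ppis_confusion")
}

#' @export
print.ppis_confusion <- function(x, ...) {
  cat("TP", x$TP, " TN", x$TN, " FP", x$FP, " FN", x$FN, "\n")
  invisible(x)
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator, returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Threshold metrics from confusion counts
#'
#' ACC, Precision, Recall, F1 and the Matthews correlation coefficient from
#' their standard closed forms.  Zero denominators yield 0 with a warning.
#'
#' @param counts A `ppis_confusion` (or list with `TP`, `TN`, `FP`, `FN`).
#' @return Tibble with one row: `acc`, `precision`, `recall`, `f1`, `mcc`.
#' @export
metrics_from_counts <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  acc <- .safe_ratio(TP + TN, TP + TN + FP + FN, "ACC")
  precision <- .safe_ratio(TP, TP + FP, "Precision")
  recall <- .safe_ratio(TP, TP + FN, "Recall")
  f1 <- .safe_ratio(2 * precision * recall, precision + recall, "F1")
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) {
    warning("MCC: zero denominator, returning 0", call. = FALSE)
    0
  } else (TP * TN - FP * FN) / mcc_den
  tibble::tibble(acc = acc, precision = precision, recall = recall,
                 f1 = f1, mcc = mcc)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted one-half — the rank-statistic equivalent of the O(n^2)
#' pairwise comparison.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary 0/1 labels.
#' @return AUROC in `[0, 1]`; 0 with a warning if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    warning("AUROC undefined with a single class, returning 0", call. = FALSE)
    return(0)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (step integral)
#'
#' Integrates precision over recall steps while sweeping the threshold down
#' through the sorted scores; tied scores enter as one block.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels.
#' @return AUPRC in `[0, 1]`; 0 with a warning if no positives exist.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  np <- sum(labels == 1)
  if (np == 0) {
    warning("AUPRC undefined without positives, returning 0", call. = FALSE)
    return(0)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cut only at distinct-score boundaries so ties enter as one block
  boundary <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(y)[boundary]
  n_called <- boundary
  recall <- tp / np
  precision <- tp / n_called
  sum(diff(c(0, recall)) * precision)
}

#' Full metric bundle from scores and labels
#'
#' Confusion-based metrics at the given threshold plus the two
#' threshold-independent ranking metrics.
#'
#' @param labels Binary 0/1 labels.
#' @param scores Probabilities/scores.
#' @param threshold Classification threshold (default 0.5).
#' @return Tibble of class `ppis_metrics`, one row: `acc`, `precision`,
#'   `recall`, `f1`, `mcc`, `auroc`, `auprc`, with the confusion counts as
#'   attribute `"counts"`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  counts <- confusion_counts(labels, as.integer(scores >= threshold))
  out <- metrics_from_counts(counts)
  out$auroc <- auroc(scores, labels)
  out$auprc <- auprc(scores, labels)
  attr(out, "counts") <- counts
  class(out) <- c("ppis_metrics", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metric bundle into long format
#'
#' @param x A `ppis_metrics` tibble.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `value`.
#' @method tidy ppis_metrics
#' @export
tidy.ppis_metrics <- function(x, ...) {
  tibble::tibble(metric = names(x), value = as.numeric(x[1, ]))
}
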