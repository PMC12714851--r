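#' Classification metrics from a confusion matrix
#'
#' Computes the confusion counts and the five standard ratios for a binary
#' task:
#' \deqn{Accuracy = (T^+ + T^-) / (T^+ + T^- + F^+ + F^-)}
#' \deqn{Sensitivity = T^+ / (T^+ + F^-)}
#' \deqn{Specificity = T^- / (T^- + F^+)}
#' \deqn{Precision = T^+ / (T^+ + F^+)}
#' \deqn{F1 = 2 \cdot Precision \cdot Sensitivity / (Precision + Sensitivity)}
#' Undefined ratios (zero denominator) are reported as 0 with the
#' corresponding name recorded in `undefined`.
#'
#' @param predictions Predicted class labels.
#' @param labels True class labels, same length.
#' @param positive The label counted as positive (default: `1` if present,
#'   else the last sorted level).
#' @param groups Optional grouping vector; when given, `by_group` holds one
#'   metrics object per group (subgroup/fairness-style evaluation).
#' @return An object of class `neuroedge_metrics`: counts `T_pos`, `T_neg`,
#'   `F_pos`, `F_neg` and ratios `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, plus `undefined` and optional `by_group`.
#' @export
evaluate <- function(predictions, labels, positive = NULL, groups = NULL) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  if (is.null(positive)) {
    lv <- sort(unique(c(as.character(labels), as.character(predictions))))
    positive <- if ("1" %in% lv) "1" else lv[length(lv)]
  }
  p <- as.character(predictions) == as.character(positive)
  y <- as.character(labels) == as.character(positive)
  tp <- sum(p & y); tn <- sum(!p & !y); fp <- sum(p & !y); fn <- sum(!p & y)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  acc <- ratio(tp + tn, tp + tn + fp + fn)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  vals <- c(accuracy = acc, sensitivity = sens, specificity = spec,
            precision = prec, f1 = f1)
  undefined <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  out <- c(list(T_pos = tp, T_neg = tn, F_pos = fp, F_neg = fn,
                positive = positive),
           as.list(vals), list(undefined = undefined))
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(labels))
    out$by_group <- lapply(split(seq_along(labels), groups), function(i) {
      evaluate(predictions[i], labels[i], positive = positive)
    })
  }
  structure(out, class = "neuroedge_metrics")
}

#' @export
print.neuroedge_metrics <- function(x, ...) {
  cat(sprintf("<metrics> n=%d  T+=%d T-=%d F+=%d F-=%d\n",
              x$T_pos + x$T_neg + x$F_pos + x$F_neg,
              x$T_pos, x$T_neg, x$F_pos, x$F_neg))
  cat(sprintf("  accuracy %.4f | sensitivity %.4f | specificity %.4f | precision %.4f | F1 %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  if (length(x$undefined)) {
    cat("  undefined (reported 0):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique scores, collecting
#' (false-positive rate, true-positive rate) points, and integrates by the
#' trapezoid rule. The result equals the pairwise concordance probability
#' (ties counted 1/2).
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary labels (the larger/`1` level is positive unless
#'   `positive` is given).
#' @param positive Positive label (see [evaluate()]).
#' @return A list: `curve` (data.frame with `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  if (is.null(positive)) {
    lv <- sort(unique(as.character(labels)))
    positive <- if ("1" %in% lv) "1" else lv[length(lv)]
  }
  y <- as.character(labels) == as.character(positive)
  if (all(y) || !any(y)) stop("roc_auc needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(y); nn <- sum(!y)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
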