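#' Confusion-matrix metrics for a binary classifier
#'
#' Computes the exact integer confusion matrix and the derived fractions
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/n`, PPV `TP/(TP+FP)` and NPV `TN/(TN+FN)`. Predictions with a
#' label outside the two classes (e.g. `"unclassifiable"`) are counted as
#' misclassifications against their true class, which keeps `n` fixed and
#' is conservative.
#'
#' For a label-only (binary) predictor the ROC curve has a single interior
#' operating point, so the AUC equals `(sensitivity + specificity) / 2`;
#' that value is included here as `auc_binary`.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive_label The case (positive) class label.
#' @param negative_label The control class label; by default the other
#'   label present in `truth`.
#' @return An object of class `class_metrics` (a list of counts and
#'   fractions).
#' @export
confusion_metrics <- function(predicted, truth, positive_label,
                              negative_label = NULL) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  if (is.null(negative_label)) {
    negative_label <- setdiff(unique(truth), positive_label)
    if (length(negative_label) != 1L) {
      stop("truth must contain exactly one class besides the positive label")
    }
  }
  unknown <- setdiff(unique(truth), c(positive_label, negative_label))
  if (length(unknown)) {
    stop("unknown true label(s): ", paste(unknown, collapse = ", "))
  }
  tp <- sum(truth == positive_label & predicted == positive_label)
  fn <- sum(truth == positive_label & predicted != positive_label)
  tn <- sum(truth == negative_label & predicted == negative_label)
  fp <- sum(truth == negative_label & predicted != negative_label)
  metrics_from_counts(tp, fn, tn, fp)
}

#' Metrics from raw confusion counts
#'
#' @param tp,fn,tn,fp Non-negative integer counts (true positive, false
#'   negative, true negative, false positive).
#' @return An object of class `class_metrics`.
#' @rdname confusion_metrics
#' @export
metrics_from_counts <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  n <- tp + fn + tn + fp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(
    TP = tp, FN = fn, TN = tn, FP = fp, n = n,
    sensitivity = sens,
    specificity = spec,
    accuracy = if (n > 0) (tp + tn) / n else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    auc_binary = mean(c(sens, spec))
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("Confusion matrix (n = %d): TP %d  FN %d  TN %d  FP %d\n",
              x$n, x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  cat(sprintf("  PPV %.2f%%  NPV %.2f%%  binary AUC %.2f%%\n",
              100 * x$ppv, 100 * x$npv, 100 * x$auc_binary))
  invisible(x)
}

#' ROC AUC with DeLong 95% confidence interval
#'
#' AUC is the Mann-Whitney probability that a random positive sample
#' scores above a random negative one, with ties contributing 1/2. The
#' confidence interval uses DeLong's asymptotic, tie-corrected method.
#' Higher scores are always taken to favour the positive class (the
#' curve's direction is fixed, not auto-selected, so an anti-predictive
#' score yields AUC < 0.5 rather than being silently flipped).
#'
#' @param scores Numeric score vector.
#' @param truth Class label vector, same length.
#' @param positive_label The positive class label.
#' @return List with `auc` and `ci95` (length-2 vector).
#' @export
roc_auc <- function(scores, truth, positive_label) {
  is_pos <- truth == positive_label
  if (!any(is_pos) || all(is_pos)) {
    stop("need at least one positive and one negative sample")
  }
  keep <- !is.na(scores)
  scores <- scores[keep]
  is_pos <- is_pos[keep]
  r <- suppressMessages(pROC::roc(
    response = is_pos, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE))
  ci <- tryCatch(suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
                 error = function(e) rep(NA_real_, 3))
  list(auc = as.numeric(pROC::auc(r)), ci95 = ci[c(1L, 3L)])
}

#' Per-class fold-change summary for a signature pair
#'
#' Summarises, per class, the within-sample expression ratio of the
#' control-high gene over the control-low gene (for an oriented signature
#' pair this is `E(low_in_case) / E(high_in_case)`). Under a reversed
#' pair this ratio sits above 1 in most control samples and below 1 in
#' most case samples, while its magnitude stays close to 1 — the reason a
#' quantitative cutoff on the ratio travels poorly across cohorts but the
#' qualitative ordering does not.
#'
#' @param mat Gene-by-sample numeric matrix (strictly positive values).
#' @param low_in_case,high_in_case Gene IDs of the oriented pair.
#' @param labels Per-sample class labels.
#' @return Data frame with one row per class: `class`, `n`, `min`,
#'   `median`, `max` of the ratio.
#' @export
fold_change_summary <- function(mat, low_in_case, high_in_case, labels) {
  check_expression_matrix(mat)
  labels <- match_labels(mat, labels)
  lo <- mat[low_in_case, ]
  hi <- mat[high_in_case, ]
  if (any(c(lo, hi) <= 0, na.rm = TRUE)) {
    stop("fold-change summary requires strictly positive expression values")
  }
  ratio <- lo / hi   # control-high over control-low
  classes <- sort(unique(labels))
  out <- do.call(rbind, lapply(classes, function(cl) {
    r <- ratio[labels == cl & !is.na(ratio)]
    data.frame(class = cl, n = length(r),
               min = min(r), median = stats::median(r), max = max(r),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
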