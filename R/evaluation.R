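# Binary-classification evaluation: confusion matrix, the derived metrics,
# Cohen's kappa interpretation bands, ROC/AUC, and the five-tier probability
# classification of pathogenicity scores.

#' Construct a confusion matrix from counts
#'
#' @param tp,tn,fp,fn non-negative counts (positive class = pathogenic).
#' @return a `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(TP = as.numeric(tp), TN = as.numeric(tn), FP = as.numeric(fp),
              FN = as.numeric(fn))
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("confusion-matrix counts must be non-negative numbers",
         call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("Predicted pathogenic", "Predicted benign"),
                              c("Actual pathogenic", "Actual benign")))
  print(m)
  invisible(x)
}

#' Count confusion-matrix cells from label vectors
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels.
#' @return a [confusion_matrix()].
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  confusion_matrix(tp = sum(y_pred == 1 & y_true == 1),
                   tn = sum(y_pred == 0 & y_true == 0),
                   fp = sum(y_pred == 1 & y_true == 0),
                   fn = sum(y_pred == 0 & y_true == 1))
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); returning 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Matthews correlation coefficient
#'
#' TP*TN - FP*FN over the geometric mean of the four marginal totals; 0 by
#' convention when any marginal is empty.
#'
#' @param cm a [confusion_matrix()].
#' @return value in \[-1, 1\].
#' @export
matthews_cc <- function(cm) {
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  den <- (tp + fp) * (tp + fn) * (tn + fn) * (tn + fp)
  if (den == 0) {
    return(0)
  }
  # product kept in log space is unnecessary at clinical cohort sizes;
  # doubles hold the counts seen here exactly
  (tp * tn - fp * fn) / sqrt(den)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e) with the expected
#' agreement p_e from the marginal products. Degenerate marginals
#' (p_e = 1) yield 1 for perfect agreement, else 0.
#'
#' @param cm a [confusion_matrix()].
#' @return value in \[-1, 1\].
#' @export
cohen_kappa <- function(cm) {
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  n <- tp + tn + fp + fn
  if (n == 0) {
    stop("empty confusion matrix", call. = FALSE)
  }
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - pe) < 1e-15) {
    return(if (po >= 1 - 1e-15) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' All scalar metrics of a confusion matrix
#'
#' Accuracy, precision, recall (sensitivity), specificity, error rate, F1,
#' MCC and Cohen's kappa, with the positive class = pathogenic. Zero
#' denominators yield 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @param auc optional AUC to carry in the report.
#' @return a `metrics_report` list.
#' @export
classification_metrics <- function(cm, auc = NA_real_) {
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  n <- tp + tn + fp + fn
  if (n == 0) {
    stop("empty confusion matrix", call. = FALSE)
  }
  accuracy <- (tp + tn) / n
  report <- list(
    accuracy = accuracy,
    precision = safe_ratio(tp, tp + fp, "precision"),
    recall = safe_ratio(tp, tp + fn, "recall"),
    specificity = safe_ratio(tn, tn + fp, "specificity"),
    error_rate = 1 - accuracy,
    f1 = safe_ratio(tp, tp + 0.5 * (fn + fp), "F1"),
    mcc = matthews_cc(cm),
    kappa = cohen_kappa(cm),
    auc = auc,
    n = n
  )
  structure(report, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat("Binary classification metrics (n =", x$n, ")\n")
  for (m in c("accuracy", "precision", "specificity", "recall", "mcc",
              "auc", "f1", "error_rate", "kappa")) {
    cat(sprintf("  %-11s %s\n", m, pct(x[[m]])))
  }
  invisible(x)
}

#' Format a metrics report as a summary-table row
#'
#' One-row data.frame in the column order Method, Accuracy, Precision,
#' Specificity, Sensitivity, MCC, AUC, F1-Score, Err — percentages at two
#' decimal places.
#'
#' @param report a `metrics_report`.
#' @param method label for the first column.
#' @return one-row data.frame.
#' @export
metrics_row <- function(report, method = "model") {
  p2 <- function(v) if (is.na(v)) NA_real_ else round(100 * v, 2)
  data.frame(Method = method,
             Accuracy = p2(report$accuracy),
             Precision = p2(report$precision),
             Specificity = p2(report$specificity),
             Sensitivity = p2(report$recall),
             MCC = p2(report$mcc),
             AUC = p2(report$auc),
             `F1-Score` = p2(report$f1),
             Err = p2(report$error_rate),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Interpretation band of a Cohen's kappa value
#'
#' Agreement bands: up to 0.20 "None", to 0.39 "Minimal", to 0.59 "Weak",
#' to 0.79 "Moderate", to 0.90 "Strong", above 0.90 "Almost perfect".
#' Negative kappa (less agreement than chance) reports "None".
#'
#' @param kappa value in \[-1, 1\].
#' @return band label.
#' @export
interpret_kappa <- function(kappa) {
  if (length(kappa) != 1L || is.na(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must be a scalar in [-1, 1]", call. = FALSE)
  }
  if (kappa <= 0.20) return("None")
  if (kappa <= 0.39) return("Minimal")
  if (kappa <= 0.59) return("Weak")
  if (kappa <= 0.79) return("Moderate")
  if (kappa <= 0.90) return("Strong")
  "Almost perfect"
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores (ties stepped
#' simultaneously), yielding points from (0,0) to (1,1), and integrates the
#' curve by the trapezoidal rule. Equivalent to the normalized
#' Mann-Whitney U statistic with ties counted half.
#'
#' @param y_true 0/1 labels, both classes present.
#' @param scores numeric scores, higher = more pathogenic.
#' @return list with `points` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to form a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index in each tie block
  tpr <- cumsum(y == 1)[keep] / n1
  fpr <- cumsum(y == 0)[keep] / n0
  pts <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

TIER_LEVELS <- c("Benign", "Likely benign", "Uncertain", "Likely pathogenic",
                 "Pathogenic")

#' Five-tier classification of a pathogenicity probability
#'
#' Contiguous intervals over \[0,1\]: below 0.001 Benign; to 0.05 Likely
#' benign; to 0.95 Uncertain; 0.95 to 0.99 Likely pathogenic; above 0.99
#' Pathogenic. Vectorized.
#'
#' @param score probability in \[0,1\].
#' @return ordered factor with the five tier levels.
#' @export
assign_tier <- function(score) {
  if (length(score) == 0L) {
    return(factor(character(), levels = TIER_LEVELS, ordered = TRUE))
  }
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  lab <- ifelse(score < 0.001, "Benign",
         ifelse(score < 0.05, "Likely benign",
         ifelse(score < 0.95, "Uncertain",
         ifelse(score <= 0.99, "Likely pathogenic", "Pathogenic"))))
  factor(lab, levels = TIER_LEVELS, ordered = TRUE)
}
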