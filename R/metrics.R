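# Evaluation metrics. Binary metrics take "abnormal" as the positive class
# (fail-safe orientation for a screening detector); multiclass metrics cover
# the six-category classifier. Degenerate denominators map to 0.

safe_div <- function(a, b) if (b == 0) 0 else a / b

#' Binary detector metrics
#'
#' Accuracy, precision, recall, F1 and Matthews correlation coefficient with
#' the \code{positive} class (default \code{"abnormal"}) as positive, plus
#' the 2x2 confusion matrix. Metrics whose denominator is zero are reported
#' as 0.
#'
#' @param truth,pred Character/factor vectors of true and predicted labels.
#' @param positive The positive-class label (default \code{"abnormal"}).
#' @return List with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}, \code{mcc} and \code{confusion}.
#' @export
binary_metrics <- function(truth, pred, positive = "abnormal") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  list(accuracy = (tp + tn) / length(truth),
       precision = precision,
       recall = recall,
       f1 = safe_div(2 * precision * recall, precision + recall),
       mcc = if (mcc_den == 0) 0 else
         (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den,
       confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                          dimnames = list(pred = c("negative", "positive"),
                                          truth = c("negative", "positive"))))
}

# one-vs-rest precision-recall curve and average precision
pr_curve <- function(scores, is_pos) {
  o <- order(scores, decreasing = TRUE)
  y <- as.integer(is_pos[o])
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  npos <- sum(y)
  # collapse tied scores to their last cumulative count
  keep <- c(diff(scores[o]) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- if (npos == 0) tp * 0 else tp / npos
  ap <- if (npos == 0) 0 else sum(diff(c(0, recall)) * precision)
  list(precision = c(1, precision), recall = c(0, recall), ap = ap)
}

# one-vs-rest ROC curve; AUC by the rank (Mann-Whitney) statistic, exact
# under ties
roc_curve <- function(scores, is_pos) {
  npos <- sum(is_pos); nneg <- sum(!is_pos)
  o <- order(scores, decreasing = TRUE)
  y <- as.integer(is_pos[o])
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(diff(scores[o]) != 0, TRUE)
  tpr <- c(0, tp[keep] / max(npos, 1))
  fpr <- c(0, fp[keep] / max(nneg, 1))
  auc <- if (npos == 0 || nneg == 0) 0 else
    (sum(rank(scores)[is_pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(tpr = tpr, fpr = fpr, auc = auc)
}

#' Multiclass classification metrics
#'
#' Accuracy, per-class precision/recall/F1, macro F1, Cohen's kappa,
#' multiclass Matthews correlation coefficient, the confusion matrix and,
#' when class probabilities are supplied, per-class one-vs-rest average
#' precision (AP) and ROC AUC with the corresponding curve points.
#'
#' @param truth True labels (character/factor).
#' @param pred Predicted labels.
#' @param probs Optional numeric matrix \code{n x n_classes} of class
#'   probabilities whose column names are the class labels.
#' @param classes Class vocabulary (defaults to the union of observed labels,
#'   or \code{colnames(probs)} when given).
#' @return An object of class \code{metrics_report}.
#' @export
multiclass_metrics <- function(truth, pred, probs = NULL, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(classes))
    classes <- if (!is.null(probs)) colnames(probs) else
      sort(unique(c(truth, pred)))
  k <- length(classes)
  cm <- table(factor(truth, classes), factor(pred, classes))
  cm <- matrix(as.numeric(cm), k, k, dimnames = list(truth = classes, pred = classes))
  n <- length(truth)
  acc <- sum(diag(cm)) / n
  per_class <- data.frame(class = classes, precision = 0, recall = 0, f1 = 0)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    per_class$precision[i] <- safe_div(tp, sum(cm[, i]))
    per_class$recall[i] <- safe_div(tp, sum(cm[i, ]))
    per_class$f1[i] <- safe_div(2 * per_class$precision[i] * per_class$recall[i],
                                per_class$precision[i] + per_class$recall[i])
  }
  # Cohen's kappa
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  # multiclass MCC (Gorodkin's R_k)
  tvec <- rowSums(cm); pvec <- colSums(cm); s <- n
  c_tr <- sum(diag(cm))
  num <- c_tr * s - sum(tvec * pvec)
  den <- sqrt(s^2 - sum(pvec^2)) * sqrt(s^2 - sum(tvec^2))
  mcc <- if (den == 0) 0 else num / den
  out <- list(accuracy = acc, per_class = per_class,
              macro_f1 = mean(per_class$f1), kappa = kappa, mcc = mcc,
              confusion = cm)
  if (!is.null(probs)) {
    stopifnot(nrow(probs) == n, ncol(probs) == k)
    pr <- lapply(seq_len(k), function(i)
      pr_curve(probs[, i], truth == classes[i]))
    roc <- lapply(seq_len(k), function(i)
      roc_curve(probs[, i], truth == classes[i]))
    names(pr) <- names(roc) <- classes
    out$ap <- vapply(pr, `[[`, numeric(1), "ap")
    out$macro_ap <- mean(out$ap)
    out$auc <- vapply(roc, `[[`, numeric(1), "auc")
    out$pr_curves <- pr
    out$roc_curves <- roc
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy %.4f | macro F1 %.4f | kappa %.4f | MCC %.4f\n",
              x$accuracy, x$macro_f1, x$kappa, x$mcc))
  if (!is.null(x$macro_ap))
    cat(sprintf("macro AP %.4f | AUC range %.4f-%.4f\n", x$macro_ap,
                min(x$auc), max(x$auc)))
  invisible(x)
}

#' Significance stars
#'
#' Maps a p-value to the conventional star annotation: * p < 0.05,
#' ** p < 0.01, *** p < 0.001, **** p < 0.0001, \code{"ns"} otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
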