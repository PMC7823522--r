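# Classification metrics computed from first principles (confusion matrix
# and rank statistics), shared by the profile cross-validation and the
# substrate classifiers.

# Binary AUC by the rank (Mann-Whitney) formula with midranks for ties.
binary_auc <- function(truth, score) {
  pos <- sum(truth == 1L); neg <- sum(truth == 0L)
  if (pos == 0L || neg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth == 1L]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' Compute classifier performance metrics
#'
#' Accuracy, error rate, multiclass Matthews correlation coefficient,
#' per-class precision/recall/F1/support, micro/macro/weighted averages and
#' (when class scores are supplied) micro- and macro-averaged one-vs-rest
#' ROC-AUC. All quantities are derived directly from the pooled confusion
#' matrix / rank statistics.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels (same length).
#' @param y_scores optional numeric matrix of class scores, one column per
#'   class (column names = class labels), one row per observation.
#' @return object of class `classifier_metrics`: a list with `$accuracy`,
#'   `$error_rate`, `$mcc`, `$per_class` (data frame), `$macro`, `$micro`,
#'   `$weighted` (each precision/recall/f1), `$auc_macro`, `$auc_micro`,
#'   `$support`.
#' @export
compute_metrics <- function(y_true, y_pred, y_scores = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  levels_all <- sort(unique(c(y_true, y_pred)))
  conf <- table(factor(y_true, levels_all), factor(y_pred, levels_all))
  n <- length(y_true)
  acc <- sum(diag(conf)) / n

  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(conf[cl, ]), stringsAsFactors = FALSE)
  }))

  # micro averages pool the binary counts; for single-label multiclass
  # classification micro precision = recall = f1 = accuracy
  tp_all <- sum(diag(conf[classes, classes, drop = FALSE]))
  fp_all <- sum(vapply(classes, function(cl) sum(conf[, cl]) - conf[cl, cl], 1))
  fn_all <- sum(vapply(classes, function(cl) sum(conf[cl, ]) - conf[cl, cl], 1))
  micro_p <- tp_all / (tp_all + fp_all)
  micro_r <- tp_all / (tp_all + fn_all)
  micro_f1 <- if (micro_p + micro_r == 0) 0 else
    2 * micro_p * micro_r / (micro_p + micro_r)

  w <- per$support / sum(per$support)
  avg <- function(col, weights = NULL) {
    if (is.null(weights)) mean(per[[col]]) else sum(per[[col]] * weights)
  }

  # multiclass MCC (covariance form over the confusion matrix)
  cm <- unclass(conf)
  tk <- rowSums(cm); pk <- colSums(cm); c0 <- sum(diag(cm)); s <- sum(cm)
  num <- c0 * s - sum(tk * pk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  mcc <- if (den == 0) NA_real_ else num / den

  auc_macro <- auc_micro <- NA_real_
  if (!is.null(y_scores) && length(classes) >= 2L) {
    y_scores <- as.matrix(y_scores)
    if (nrow(y_scores) != n) stop("y_scores must have one row per observation")
    aucs <- vapply(classes, function(cl) {
      if (!cl %in% colnames(y_scores)) return(NA_real_)
      binary_auc(as.integer(y_true == cl), y_scores[, cl])
    }, 1)
    auc_macro <- mean(aucs, na.rm = TRUE)
    pres <- intersect(classes, colnames(y_scores))
    ind <- as.vector(vapply(pres, function(cl) as.integer(y_true == cl),
                            integer(n)))
    auc_micro <- binary_auc(ind, as.vector(y_scores[, pres]))
  }

  structure(list(
    accuracy = acc, error_rate = 1 - acc, mcc = mcc, per_class = per,
    micro = c(precision = micro_p, recall = micro_r, f1 = micro_f1),
    macro = c(precision = avg("precision"), recall = avg("recall"),
              f1 = avg("f1")),
    weighted = c(precision = avg("precision", w), recall = avg("recall", w),
                 f1 = avg("f1", w)),
    auc_macro = auc_macro, auc_micro = auc_micro,
    support = sum(per$support)), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  error %.3f  MCC %s\n", x$accuracy, x$error_rate,
              ifelse(is.na(x$mcc), "NA", sprintf("%.3f", x$mcc))))
  cat(sprintf("micro P/R/F1: %.3f/%.3f/%.3f  macro F1: %.3f  weighted F1: %.3f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"],
              x$macro["f1"], x$weighted["f1"]))
  if (!is.na(x$auc_macro))
    cat(sprintf("ROC-AUC macro %.3f  micro %.3f\n", x$auc_macro, x$auc_micro))
  invisible(x)
}
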