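# Multiclass evaluation: K x K confusion matrix, one-vs-rest per-class
# metrics, macro averages, ROC/AUC.
#
# Two accuracy conventions are computed and labeled: the pooled accuracy
# (1/N) * sum I(yhat = y) = trace(confusion)/N, and the macro accuracy
# (unweighted mean of the per-class one-vs-rest accuracies), which is the
# headline convention here.  The headline macro F1 is the harmonic mean of
# macro precision and macro recall; the mean of per-class F1 values is
# also reported as `macro_f1_classmean`.

#' Confusion matrix from label-id vectors
#'
#' @param y_true,y_pred Integer ids in `[0, K)`, equal length.
#' @param k Number of classes.
#' @param labels Optional class names for dimnames.
#' @return K x K count matrix, rows = true, cols = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, k, labels = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0) {
    warning("empty inputs: N = 0")
    return(matrix(0L, k, k, dimnames = list(labels, labels)))
  }
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= k)) {
    stop("label ids out of range [0, ", k, ")")
  }
  cm <- matrix(0L, k, k, dimnames = list(labels, labels))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

#' Per-class one-vs-rest metrics
#'
#' For each class c, TP/FP/FN/TN by one-vs-rest collapse, then
#' `Acc = (TP+TN)/N`, `Sen = TP/(TP+FN)`, `Spe = TN/(TN+FP)`,
#' `Pre = TP/(TP+FP)`, `F1 = 2*Pre*Sen/(Pre+Sen)`.  Zero-denominator
#' metrics are reported as 0 with a TRUE entry in the `undefined` matrix.
#'
#' @param confusion K x K count matrix (rows = true).
#' @return Data frame (one row per class) with the metrics and attribute
#'   `undefined`.
#' @export
per_class_metrics <- function(confusion) {
  n <- sum(confusion)
  stopifnot(n >= 1)
  k <- nrow(confusion)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  rows <- lapply(seq_len(k), function(c) {
    tp <- confusion[c, c]
    fp <- sum(confusion[-c, c])
    fn <- sum(confusion[c, -c])
    tn <- n - tp - fp - fn
    pre <- safe(tp, tp + fp)
    sen <- safe(tp, tp + fn)
    f1 <- if (is.na(pre) || is.na(sen) || (pre + sen) == 0) NA_real_ else
      2 * pre * sen / (pre + sen)
    data.frame(accuracy = (tp + tn) / n,
               sensitivity = sen, specificity = safe(tn, tn + fp),
               precision = pre, f1 = f1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- rownames(confusion) %||% paste0("class", seq_len(k) - 1)
  undef <- is.na(as.matrix(out))
  out[is.na(out)] <- 0
  attr(out, "undefined") <- undef
  out
}

#' Macro and pooled overall metrics
#'
#' @param confusion K x K count matrix.
#' @return Named list: `pooled_accuracy` (trace/N), `macro_accuracy`
#'   (mean one-vs-rest accuracy; the headline convention),
#'   `macro_precision`, `macro_recall`, `macro_f1` (harmonic mean of
#'   macro precision and recall) and `macro_f1_classmean`.
#' @export
overall_metrics <- function(confusion) {
  pc <- per_class_metrics(confusion)
  mp <- mean(pc$precision)
  mr <- mean(pc$sensitivity)
  list(
    pooled_accuracy = sum(diag(confusion)) / sum(confusion),
    macro_accuracy = mean(pc$accuracy),
    macro_precision = mp,
    macro_recall = mr,
    macro_f1 = if ((mp + mr) == 0) 0 else 2 * mp * mr / (mp + mr),
    macro_f1_classmean = mean(pc$f1)
  )
}

#' One-vs-rest ROC curves and AUC
#'
#' Threshold sweep over the unique scores of each class; AUC by the
#' trapezoid rule.  A class absent from (or filling all of) `y_true` gets
#' an NA AUC.
#'
#' @param scores n x K matrix of class probabilities (rows sum to 1).
#' @param y_true Integer ids in `[0, K)`.
#' @return List per class: data frame `roc` (fpr, tpr, threshold) and
#'   `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  stopifnot(nrow(scores) == length(y_true), ncol(scores) >= 2)
  if (max(abs(rowSums(scores) - 1)) > 1e-6) {
    stop("score rows must sum to 1")
  }
  lapply(seq_len(ncol(scores)), function(c) {
    pos <- y_true == (c - 1)
    if (!any(pos) || all(pos)) {
      return(list(roc = NULL, auc = NA_real_))
    }
    sc <- scores[, c]
    thr <- c(Inf, sort(unique(sc), decreasing = TRUE))
    np <- sum(pos); nn <- sum(!pos)
    tpr <- vapply(thr, function(t) sum(sc >= t & pos) / np, numeric(1))
    fpr <- vapply(thr, function(t) sum(sc >= t & !pos) / nn, numeric(1))
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
  })
}

#' Assemble a full evaluation report
#'
#' @param y_true,y_pred Integer ids in `[0, K)`.
#' @param scores Optional n x K probability matrix for ROC/AUC.
#' @param labels Optional class names.
#' @return Object of class `evaluation_report`.
#' @export
evaluation_report <- function(y_true, y_pred, scores = NULL, labels = NULL) {
  k <- if (!is.null(scores)) ncol(scores) else max(c(y_true, y_pred)) + 1L
  if (!is.null(labels)) k <- length(labels)
  cm <- confusion_matrix(y_true, y_pred, k, labels)
  roc <- if (!is.null(scores)) roc_auc(scores, y_true) else NULL
  structure(list(
    confusion = cm,
    per_class = per_class_metrics(cm),
    overall = overall_metrics(cm),
    roc = roc,
    auc = if (!is.null(roc)) vapply(roc, `[[`, numeric(1), "auc") else NULL,
    n = length(y_true)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  cat("\nPer-class metrics:\n")
  pc <- x$per_class
  tab <- t(round(as.matrix(pc), 4))
  rownames(tab) <- c("Acc", "Sen", "Spe", "Pre", "F1 score")
  print(tab)
  ov <- x$overall
  cat(sprintf("\nMacro: Acc %.4f  Pre %.4f  Rec %.4f  F1 %.4f  (pooled Acc %.4f)\n",
              ov$macro_accuracy, ov$macro_precision, ov$macro_recall,
              ov$macro_f1, ov$pooled_accuracy))
  if (!is.null(x$auc)) {
    cat("AUC:", paste(sprintf("%.4f", x$auc), collapse = " "), "\n")
  }
  invisible(x)
}

#' Write an evaluation report to JSON (+ ROC points CSV)
#' @param report An `evaluation_report`.
#' @param path JSON output path.
#' @param roc_csv Optional CSV path for ROC points.
#' @export
write_report <- function(report, path, roc_csv = NULL) {
  payload <- list(
    confusion = unclass(report$confusion),
    per_class = report$per_class,
    overall = report$overall,
    auc = report$auc,
    n = report$n
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  if (!is.null(roc_csv) && !is.null(report$roc)) {
    pts <- do.call(rbind, lapply(seq_along(report$roc), function(c) {
      r <- report$roc[[c]]$roc
      if (is.null(r)) return(NULL)
      cbind(class = c - 1L, r)
    }))
    utils::write.csv(pts, roc_csv, row.names = FALSE)
  }
  invisible(path)
}
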