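## Multiclass evaluation suite: confusion matrix, one-vs-rest per-class
## precision/recall/F1, accuracy, macro and weighted averages, and
## one-vs-rest ROC curves with trapezoid AUC.

#' Confusion matrix (rows = true class, columns = predicted class)
#'
#' @param true,pred equal-length integer label vectors.
#' @param levels class labels defining the matrix dimensions (default 0:2,
#'   the three risk classes).
#' @return Integer matrix with dimnames `true`/`predicted`; its total is
#'   the sample count.
#' @export
confusion_matrix <- function(true, pred, levels = 0:2) {
  if (length(true) != length(pred)) {
    stop(sprintf("length mismatch: %d true vs %d predicted labels",
                 length(true), length(pred)), call. = FALSE)
  }
  m <- table(factor(true, levels = levels),
             factor(pred, levels = levels))
  m <- matrix(as.integer(m), length(levels), length(levels),
              dimnames = list(true = as.character(levels),
                              predicted = as.character(levels)))
  m
}

#' One-vs-rest precision, recall and F1 for one class
#'
#' `TP` is the diagonal cell, `FP` the rest of the predicted column, `FN`
#' the rest of the true row; `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)` (the harmonic mean, i.e. the
#' F-measure with scale factor beta = 1). Empty denominators yield 0.
#'
#' @param confusion a [confusion_matrix()].
#' @param class class label (must be one of the matrix's levels).
#' @return Named list `precision`, `recall`, `f1`.
#' @export
class_metrics <- function(confusion, class) {
  idx <- match(as.character(class), rownames(confusion))
  if (is.na(idx)) stop("class ", class, " not in confusion matrix",
                       call. = FALSE)
  tp <- confusion[idx, idx]
  fp <- sum(confusion[, idx]) - tp
  fn <- sum(confusion[idx, ]) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Overall accuracy
#'
#' Trace over total: the fraction of samples whose predicted class equals
#' the true class (the multiclass generalization of
#' `(TP + TN) / (TP + TN + FP + FN)`).
#'
#' @param confusion a [confusion_matrix()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(confusion) {
  sum(diag(confusion)) / sum(confusion)
}

#' Macro averages of per-class metrics
#'
#' Unweighted arithmetic means over classes, treating each class equally
#' (which makes the macro figures sensitive to minority-class performance).
#' `macro_f1` is the mean of per-class F1 values; the alternative
#' construction `2 * MacroP * MacroR / (MacroP + MacroR)` (harmonic
#' combination of the macro precision and recall) is returned alongside as
#' `macro_f1_pr` since the two differ whenever per-class performance is
#' uneven.
#'
#' @param per_class data.frame/list with `precision`, `recall`, `f1` per
#'   class.
#' @return Named list `macro_precision`, `macro_recall`, `macro_f1`,
#'   `macro_f1_pr`.
#' @export
macro_average <- function(per_class) {
  per_class <- as.data.frame(per_class)
  mp <- mean(per_class$precision)
  mr <- mean(per_class$recall)
  list(macro_precision = mp,
       macro_recall = mr,
       macro_f1 = mean(per_class$f1),
       macro_f1_pr = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0)
}

#' Class-size-weighted averages of per-class metrics
#'
#' @param per_class as in [macro_average()].
#' @param class_sizes per-class sample counts (weights are normalized to
#'   sum to 1).
#' @return Named list `weighted_precision`, `weighted_recall`,
#'   `weighted_f1`.
#' @export
weighted_average <- function(per_class, class_sizes) {
  per_class <- as.data.frame(per_class)
  w <- class_sizes / sum(class_sizes)
  list(weighted_precision = sum(w * per_class$precision),
       weighted_recall = sum(w * per_class$recall),
       weighted_f1 = sum(w * per_class$f1))
}

## ROC curve for one binary problem by sweeping score thresholds.
## Points are (FPR, TPR) pairs from +Inf down through every distinct score,
## so the curve runs from (0,0) to (1,1); ties in scores collapse into one
## point and the AUC is the trapezoid area (equivalently, the Mann-Whitney
## pair-counting statistic with ties counted 1/2).
binary_roc <- function(positive, scores) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  s <- scores[ord]
  n_pos <- sum(positive)
  n_neg <- length(positive) - n_pos
  keep <- c(diff(s) != 0, TRUE)   # last point of each tie group
  tpr <- c(0, cumsum(pos)[keep] / max(n_pos, 1L))
  fpr <- c(0, cumsum(!pos)[keep] / max(n_neg, 1L))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + tpr[-1L]) / 2)
  list(points = data.table::data.table(fpr = fpr, tpr = tpr), auc = auc)
}

#' One-vs-rest ROC curves and macro AUC
#'
#' For each class, that class is treated as positive and its score column
#' swept over all thresholds to trace (FPR, TPR) points; per-class AUC is
#' the trapezoid area and the macro AUC the unweighted mean over classes.
#' Constant scores for a class produce a degenerate diagonal curve (AUC
#' 0.5) with a warning.
#'
#' @param true integer label vector.
#' @param scores matrix of per-class scores with one column per class
#'   (columns named by label; rows should sum to 1 for vote fractions).
#' @param levels class labels (default 0:2).
#' @return List with `roc` (per-class list of point tables), `auc`
#'   (named per-class vector) and `macro_auc`.
#' @export
roc_auc <- function(true, scores, levels = 0:2) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(true))
  out <- list()
  aucs <- numeric(length(levels))
  names(aucs) <- as.character(levels)
  for (i in seq_along(levels)) {
    cl <- levels[i]
    col <- if (!is.null(colnames(scores)))
      match(as.character(cl), colnames(scores)) else i
    sc <- scores[, col]
    if (length(unique(sc)) == 1L) {
      warning("degenerate ROC for class ", cl,
              ": constant scores, AUC set to 0.5", call. = FALSE)
      out[[as.character(cl)]] <- data.table::data.table(fpr = c(0, 1),
                                                        tpr = c(0, 1))
      aucs[i] <- 0.5
      next
    }
    r <- binary_roc(true == cl, sc)
    out[[as.character(cl)]] <- r$points
    aucs[i] <- r$auc
    if (r$auc < 0.5) {
      warning("AUC for class ", cl, " is below chance (",
              signif(r$auc, 3), "): scores rank the class backwards",
              call. = FALSE)
    }
  }
  list(roc = out, auc = aucs, macro_auc = mean(aucs))
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, per-class precision/recall/F1, accuracy,
#' macro and weighted averages and (when scores are supplied) one-vs-rest
#' ROC/AUC into a single report. The weighted recall always equals the
#' accuracy (both are the fraction of correctly classified samples).
#'
#' @param true,pred integer label vectors.
#' @param scores optional per-class score matrix for ROC/AUC.
#' @param levels class labels (default 0:2).
#' @return An object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(true, pred, scores = NULL, levels = 0:2) {
  confusion <- confusion_matrix(true, pred, levels = levels)
  per_class <- data.table::rbindlist(lapply(levels, function(cl)
    c(list(class = cl), class_metrics(confusion, cl))))
  macro <- macro_average(per_class)
  sizes <- rowSums(confusion)
  weighted <- weighted_average(per_class, sizes)
  roc <- if (!is.null(scores)) roc_auc(true, scores, levels = levels)
  structure(list(confusion = confusion,
                 per_class = per_class,
                 accuracy = accuracy(confusion),
                 macro = macro,
                 weighted = weighted,
                 class_sizes = sizes,
                 roc = roc$roc, auc = roc$auc, macro_auc = roc$macro_auc,
                 n = length(true)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation on %d samples: accuracy %.2f%%\n",
              x$n, 100 * x$accuracy))
  tab <- as.data.frame(x$per_class)
  tab[-1] <- lapply(tab[-1], round, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("macro    P/R/F1: %.2f %.2f %.2f\n",
              x$macro$macro_precision, x$macro$macro_recall,
              x$macro$macro_f1))
  cat(sprintf("weighted P/R/F1: %.2f %.2f %.2f\n",
              x$weighted$weighted_precision, x$weighted$weighted_recall,
              x$weighted$weighted_f1))
  if (!is.null(x$macro_auc)) {
    cat(sprintf("macro AUC (one-vs-rest): %.2f\n", x$macro_auc))
  }
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param report an `evaluation_report`.
#' @param path output JSON path (full precision; the printed report rounds
#'   to 2 decimals).
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(
    n = report$n,
    confusion = unclass(report$confusion),
    per_class = report$per_class,
    accuracy = report$accuracy,
    macro = report$macro,
    weighted = report$weighted,
    auc = as.list(report$auc),
    macro_auc = report$macro_auc
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
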