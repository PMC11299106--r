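#' Confusion matrix
#'
#' Counts of samples by (true class, predicted class), rows = truth.
#'
#' @param trueLabels,predictedLabels Equal-length label vectors.
#' @param classes Class order for rows/columns (default: sorted union).
#' @return Integer matrix with `classes` as dimnames.
#' @export
confusionCounts <- function(trueLabels, predictedLabels, classes = NULL) {
  stopifnot(length(trueLabels) == length(predictedLabels),
            length(trueLabels) >= 1L)
  if (is.null(classes)) classes <- sort(unique(c(trueLabels, predictedLabels)))
  unknown <- setdiff(unique(c(trueLabels, predictedLabels)), classes)
  if (length(unknown))
    stop("label(s) outside the class order: ", paste(unknown, collapse = ", "))
  t <- factor(trueLabels, levels = classes)
  p <- factor(predictedLabels, levels = classes)
  m <- table(t, p)
  cm <- matrix(as.integer(m), length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  cm
}

#' Overall accuracy and Cohen's kappa
#'
#' Observed accuracy is the diagonal fraction Po = trace/N; the expected
#' accuracy under chance agreement is Pe = sum_i(row_i * col_i)/N^2, and
#' kappa = (Po - Pe)/(1 - Pe).
#'
#' @param cm Confusion matrix from [confusionCounts()].
#' @return List with `accuracy`, `expected_accuracy`, `kappa`, `n`.
#' @export
overallMetrics <- function(cm) {
  N <- sum(cm)
  stopifnot(N >= 1)
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (pe >= 1)
    stop("expected accuracy is 1 (degenerate single-cell matrix); ",
         "kappa is undefined")
  list(accuracy = po, expected_accuracy = pe,
       kappa = (po - pe) / (1 - pe), n = N)
}

#' Per-class one-vs-rest metrics
#'
#' One-vs-rest tallies for `targetClass` give TPR (sensitivity/recall), TNR
#' (specificity) and precision, from which balanced accuracy
#' `(TPR + TNR)/2`, the harmonic mean `2*Sn*Sp/(Sn + Sp)` and the F1 score
#' `2*precision*recall/(precision + recall)` are derived. Vanishing
#' denominators (class never true, or never predicted) yield 0 with
#' `degenerate = TRUE`.
#'
#' @param cm Confusion matrix from [confusionCounts()].
#' @param targetClass A class label present in the matrix dimnames.
#' @return List with `tpr`, `tnr`, `precision`, `balanced_accuracy`,
#'   `harmonic_mean`, `f1`, `degenerate`.
#' @export
classMetrics <- function(cm, targetClass) {
  classes <- rownames(cm)
  if (!targetClass %in% classes) stop("unknown class: ", targetClass)
  i <- match(targetClass, classes)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  degenerate <- (tp + fn) == 0 || (tp + fp) == 0 || (tn + fp) == 0
  div <- function(a, b) if (b == 0) 0 else a / b
  tpr <- div(tp, tp + fn)
  tnr <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  list(tpr = tpr, tnr = tnr, precision = prec,
       balanced_accuracy = (tpr + tnr) / 2,
       harmonic_mean = div(2 * tpr * tnr, tpr + tnr),
       f1 = div(2 * prec * tpr, prec + tpr),
       degenerate = degenerate)
}

#' One-vs-rest ROC curve and AUC
#'
#' Builds the ROC curve by sweeping the decision threshold over all unique
#' scores (highest first), and computes the AUC by the trapezoid rule. With
#' tied scores the curve moves diagonally, so the trapezoid AUC equals the
#' Mann-Whitney pair statistic with ties counted one half.
#'
#' @param scores Numeric scores for the target class, higher = more positive.
#' @param truth Logical (or 0/1) vector: `TRUE` for the target class.
#' @return List with `points` (data.frame of `fpr`, `tpr`, one row per
#'   threshold plus the (0,0) origin) and `auc`.
#' @export
rocCurve <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC requires both positive and negative samples; AUC is undefined")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each unique score
  tpr <- cumsum(y)[last] / nPos
  fpr <- cumsum(!y)[last] / nNeg
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Evaluate fragment predictions against truth
#'
#' Convenience wrapper computing the full evaluation suite from a
#' predictions table ([predictMob()]) and true labels: overall accuracy and
#' kappa, per-class metrics, and one-vs-rest ROC/AUC per class from the
#' score columns. Unclassified fragments are excluded from the confusion
#' matrix but reported in `n_unclassified`.
#'
#' @param predictions Data.frame from [predictMob()].
#' @param trueLabels Character vector of true classes, parallel to
#'   `predictions` rows.
#' @param classes Class order (default [mobClasses()]).
#' @return List with `overall`, `per_class` (data.frame), `roc` (named list
#'   of [rocCurve()] results), `confusion`, `n_unclassified`.
#' @export
evaluatePredictions <- function(predictions, trueLabels,
                                classes = mobClasses()) {
  stopifnot(nrow(predictions) == length(trueLabels))
  ok <- predictions$predicted_class != "unclassified"
  cm <- confusionCounts(trueLabels[ok], predictions$predicted_class[ok],
                        classes)
  per <- do.call(rbind, lapply(classes, function(cl) {
    m <- classMetrics(cm, cl)
    data.frame(class = cl, tpr = m$tpr, tnr = m$tnr, precision = m$precision,
               balanced_accuracy = m$balanced_accuracy,
               harmonic_mean = m$harmonic_mean, f1 = m$f1,
               degenerate = m$degenerate, stringsAsFactors = FALSE)
  }))
  roc <- list()
  for (cl in classes) {
    truth <- trueLabels[ok] == cl
    if (any(truth) && !all(truth))
      roc[[cl]] <- rocCurve(predictions[ok, cl], truth)
  }
  list(overall = overallMetrics(cm), per_class = per, roc = roc,
       confusion = cm, n_unclassified = sum(!ok))
}
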