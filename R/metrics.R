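#' Confusion-matrix classification metrics
#'
#' With MS as the positive class: accuracy `(TP+TN)/(TP+TN+FP+FN)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, `F1 = 2 PREC SEN/(PREC+SEN)`, and false positive rate
#' `FP/(FP+TN)`. Undefined ratios (zero denominator) are returned as `NaN`.
#'
#' @param TP,TN,FP,FN Confusion counts.
#' @return One-row tibble of the counts and ratios.
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  rat <- function(num, den) ifelse(den > 0, num / den, NaN)
  SEN <- rat(TP, TP + FN)
  SPE <- rat(TN, TN + FP)
  PREC <- rat(TP, TP + FP)
  F1 <- ifelse(is.finite(PREC) & is.finite(SEN) & (PREC + SEN) > 0,
               2 * PREC * SEN / (PREC + SEN), NaN)
  tibble::tibble(
    TP = TP, TN = TN, FP = FP, FN = FN,
    ACC = rat(TP + TN, TP + TN + FP + FN),
    SEN = SEN, SPE = SPE, PREC = PREC, F1 = F1,
    FPR = rat(FP, FP + TN)
  )
}

#' ROC curve and area under it
#'
#' Sweeps a decision threshold over the scores (larger score = more
#' MS-like), producing `(FPR, SEN)` points from (0,0) to (1,1) with
#' non-decreasing FPR; AUC by trapezoidal integration. Invariant under any
#' strictly increasing transformation of the scores.
#'
#' @param scores Numeric decision scores.
#' @param labels Labels (`"healthy"`/`"MS"`); MS positive.
#' @return List with `roc` (tibble `threshold`, `FPR`, `SEN`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- factor(labels, levels = c("healthy", "MS"))
  pos <- labels == "MS"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) {
    warning("single-class label set: ROC undefined", call. = FALSE)
    return(list(roc = tibble::tibble(threshold = numeric(), FPR = numeric(),
                                     SEN = numeric()), auc = NaN))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  sen <- c(0, tp[last] / nP)
  fpr <- c(0, fp[last] / nN)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(sen, -1) + utils::tail(sen, -1)) / 2)
  list(roc = tibble::tibble(threshold = thr, FPR = fpr, SEN = sen), auc = auc)
}

#' Evaluate a trained classifier on a test set
#'
#' Hard predictions give the confusion counts and ratio metrics; the signed
#' decision scores give the ROC curve and its trapezoidal AUC. MS is the
#' positive class. A single-class test set leaves SEN or SPE (and the ROC)
#' undefined, reported as `NaN` with a warning.
#'
#' @param model A fitted SVM (from [loo_grid_search()] or [fit_svm()]
#'   internals).
#' @param test_features Matrix of test rows.
#' @param test_labels Labels (`"healthy"`/`"MS"`).
#' @return An object of class `eval_metrics`: `metrics` (one-row tibble),
#'   `roc` tibble, `auc`, `predictions` tibble.
#' @export
evaluate_classifier <- function(model, test_features, test_labels) {
  test_features <- as.matrix(test_features)
  if (nrow(test_features) == 0L) stop("empty test set", call. = FALSE)
  test_labels <- factor(test_labels, levels = c("healthy", "MS"))
  pr <- predict_svm(model, test_features)
  TP <- sum(pr$label == "MS" & test_labels == "MS")
  TN <- sum(pr$label == "healthy" & test_labels == "healthy")
  FP <- sum(pr$label == "MS" & test_labels == "healthy")
  FN <- sum(pr$label == "healthy" & test_labels == "MS")
  if (length(unique(test_labels)) < 2L) {
    warning("single-class test set: SEN or SPE undefined", call. = FALSE)
  }
  rc <- suppressWarnings(roc_curve(pr$score, test_labels))
  m <- confusion_metrics(TP, TN, FP, FN)
  m$AUC <- rc$auc
  structure(
    list(metrics = m, roc = rc$roc, auc = rc$auc,
         predictions = tibble::tibble(truth = test_labels,
                                      predicted = pr$label,
                                      score = pr$score)),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<eval_metrics> n = %d | ACC %.3f SEN %.3f SPE %.3f PREC %.3f F1 %.3f AUC %.3f\n",
    m$TP + m$TN + m$FP + m$FN, m$ACC, m$SEN, m$SPE, m$PREC, m$F1, m$AUC
  ))
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x An `eval_metrics` object.
#' @param ... Unused.
#' @method tidy eval_metrics
#' @export
tidy.eval_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname evaluate_classifier
#' @method glance eval_metrics
#' @export
glance.eval_metrics <- function(x, ...) x$metrics

#' ROC plot
#' @param object An `eval_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eval_metrics
#' @export
autoplot.eval_metrics <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$FPR, .data$SEN)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate",
                  y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}
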