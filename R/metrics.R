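#' Confusion matrix of a prediction set
#'
#' Square table of (true, predicted) tallies over the union of observed true
#' and predicted categories, ordered alphabetically.
#'
#' @param predictions data frame with `true` and `predicted` columns.
#' @return matrix of class `acc_confusion` (rows: true, columns: predicted).
#' @export
confusion <- function(predictions) {
  stopifnot(nrow(predictions) >= 1)
  cats <- sort(union(predictions$true, predictions$predicted))
  cm <- table(factor(predictions$true, levels = cats),
              factor(predictions$predicted, levels = cats))
  structure(unclass(cm), class = "acc_confusion",
            dimnames = list(true = cats, predicted = cats))
}

#' Per-category one-vs-rest metrics
#'
#' For category `c`: `TP = cm[c,c]`, `FP` the column sum off the diagonal,
#' `FN` the row sum off the diagonal, `TN` everything else. Then
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)` — note the true negatives in both
#' numerator and denominator, so this is the one-vs-rest proportion of all
#' predictions classified correctly, positively or negatively, not the
#' global multiclass accuracy — `precision = TP/(TP+FP)` and
#' `recall = TP/(TP+FN)`. A zero denominator (category never predicted, or
#' never truly present) yields `NA` for the affected ratio.
#'
#' @param cm an [confusion()] matrix.
#' @param category category name.
#' @return named numeric `c(accuracy, precision, recall)`.
#' @export
category_metrics <- function(cm, category) {
  cats <- rownames(cm)
  if (!category %in% cats) stop("unknown category: ", category)
  tp <- cm[category, category]
  fp <- sum(cm[, category]) - tp
  fn <- sum(cm[category, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = ratio(tp + tn, tp + tn + fp + fn),
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn))
}

#' Metrics report: per-category and overall
#'
#' Builds the per-category one-vs-rest accuracy/precision/recall table from
#' a prediction set (or a ready confusion matrix) together with the overall
#' row, defined as the unweighted arithmetic mean over categories with
#' defined metrics.
#'
#' @param x a prediction data frame or an `acc_confusion`.
#' @return object of class `metrics_report`: list with `confusion`,
#'   `per_category` (data frame) and `overall` (named numeric).
#' @export
metrics_report <- function(x) {
  cm <- if (inherits(x, "acc_confusion")) x else confusion(x)
  cats <- rownames(cm)
  per <- t(vapply(cats, function(cc) category_metrics(cm, cc), numeric(3)))
  per_category <- data.frame(category = cats, n = rowSums(cm),
                             accuracy = per[, "accuracy"],
                             precision = per[, "precision"],
                             recall = per[, "recall"],
                             row.names = NULL, stringsAsFactors = FALSE)
  structure(list(confusion = cm, per_category = per_category,
                 overall = overall_metrics(per_category)),
            class = "metrics_report")
}

#' Overall metrics as category means
#'
#' The overall predictability metrics are the unweighted arithmetic means of
#' the per-category results, skipping categories whose ratio is undefined.
#'
#' @param per_category data frame with `accuracy`, `precision`, `recall`
#'   columns (or a `metrics_report`).
#' @return named numeric `c(accuracy, precision, recall)`.
#' @export
overall_metrics <- function(per_category) {
  if (inherits(per_category, "metrics_report"))
    per_category <- per_category$per_category
  c(accuracy = mean(per_category$accuracy, na.rm = TRUE),
    precision = mean(per_category$precision, na.rm = TRUE),
    recall = mean(per_category$recall, na.rm = TRUE))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_category, digits = 3)
  cat(sprintf("overall: accuracy %.3f  precision %.3f  recall %.3f\n",
              x$overall[["accuracy"]], x$overall[["precision"]],
              x$overall[["recall"]]))
  invisible(x)
}

#' Paired comparison of two devices' per-category accuracies
#'
#' Classical paired t-test on the per-category accuracy differences of the
#' same categories measured on two devices (`stats::t.test(paired = TRUE)`),
#' with `df = pairs - 1`. Both the two-sided p-value and the one-sided value
#' for "device 1 better" are reported. If every difference is zero the
#' statistic is 0 with p 1; a constant nonzero difference has an infinite
#' statistic (sd of differences is 0) and p 0.
#'
#' @param acc_device1,acc_device2 per-category accuracy vectors, same
#'   category order (matched by names when both are named).
#' @return list `(t, df, p_two_sided, p_one_sided_greater, mean_difference)`.
#' @export
paired_device_comparison <- function(acc_device1, acc_device2) {
  if (!is.null(names(acc_device1)) && !is.null(names(acc_device2))) {
    common <- intersect(names(acc_device1), names(acc_device2))
    acc_device1 <- acc_device1[common]
    acc_device2 <- acc_device2[common]
  }
  n <- length(acc_device1)
  if (n < 2 || length(acc_device2) != n)
    stop("need at least 2 paired categories")
  d <- acc_device1 - acc_device2
  # guard against numerically constant differences, which t.test rejects
  se <- stats::sd(d) / sqrt(n)
  if (se <= 10 * .Machine$double.eps * max(abs(mean(d)), 1e-300)) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p2 <- if (mean(d) == 0) 1 else 0
    p1 <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 1
    return(list(t = t_stat, df = n - 1, p_two_sided = p2,
                p_one_sided_greater = p1, mean_difference = mean(d)))
  }
  tt <- stats::t.test(acc_device1, acc_device2, paired = TRUE)
  t1 <- stats::t.test(acc_device1, acc_device2, paired = TRUE,
                      alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, p_one_sided_greater = t1$p.value,
       mean_difference = unname(tt$estimate))
}
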