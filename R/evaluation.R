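#' Confusion matrix between a ground-truth and a predicted timeline
#'
#' Rows are truth, columns are prediction, in the fixed class order
#' SG+D, D, SG, Other. Evaluation never truncates: lengths must match.
#'
#' @param truth,pred [interaction_timeline()] objects on the same grid
#' @return a 4x4 integer matrix of class `interaction_cm`
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(inherits(truth, "interaction_timeline"),
            inherits(pred, "interaction_timeline"))
  if (length(truth$labels) != length(pred$labels))
    stop_input("truth and prediction lengths differ (",
               length(truth$labels), " vs ", length(pred$labels), ")")
  if (!isTRUE(all.equal(truth$window_seconds, pred$window_seconds)))
    stop_input("truth and prediction window grids differ")
  cm <- table(factor(truth$labels, INTERACTION_CLASSES),
              factor(pred$labels, INTERACTION_CLASSES))
  m <- matrix(as.integer(cm), 4, 4,
              dimnames = list(truth = INTERACTION_CLASSES,
                              prediction = INTERACTION_CLASSES))
  class(m) <- c("interaction_cm", class(m))
  m
}

#' Per-class and support-weighted classification metrics
#'
#' Precision is the diagonal over the column sum, recall the diagonal over the
#' row sum, F1 their harmonic mean; each is defined as 0 when its denominator
#' is 0. Support is the ground-truth row sum. Weighted metrics average the
#' per-class values with weights proportional to support, so the weighted
#' recall equals the overall accuracy by construction.
#'
#' @param cm an [confusion_matrix()] result (or any 4x4 matrix in class order)
#' @return a `classification_report`: list with `per_class` (data.frame of
#'   precision/recall/f1/support per class), `accuracy`, and
#'   `weighted` (precision/recall/f1)
#' @export
classification_report <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != 4 || ncol(m) != 4)
    stop_input("confusion matrix must be 4x4 in class order")
  total <- sum(m)
  if (total == 0) stop_input("empty confusion matrix")
  d <- diag(m)
  colsum <- colSums(m)
  rowsum <- rowSums(m)
  precision <- ifelse(colsum > 0, d / colsum, 0)
  recall <- ifelse(rowsum > 0, d / rowsum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  support <- rowsum
  structure(list(
    per_class = data.frame(class = INTERACTION_CLASSES,
                           precision = unname(precision),
                           recall = unname(recall),
                           f1 = unname(f1),
                           support = as.integer(unname(support)),
                           stringsAsFactors = FALSE),
    accuracy = sum(d) / total,
    weighted = weighted_metrics(precision, recall, f1, support)
  ), class = "classification_report")
}

#' Support-weighted metric row
#'
#' The weighted score of a metric is the support-weighted mean of its
#' per-class values; this is the arithmetic behind the "weighted score" row
#' of a per-class performance table.
#'
#' @param precision,recall,f1 per-class metric vectors
#' @param support per-class ground-truth counts (weights)
#' @return named list with weighted precision, recall and f1
#' @export
weighted_metrics <- function(precision, recall, f1, support) {
  w <- support / sum(support)
  list(precision = sum(w * precision),
       recall = sum(w * recall),
       f1 = sum(w * f1))
}

#' @export
print.classification_report <- function(x, ...) {
  df <- x$per_class
  df$precision <- sprintf("%.2f", round_half_away(df$precision, 2))
  df$recall <- sprintf("%.2f", round_half_away(df$recall, 2))
  df$f1 <- sprintf("%.2f", round_half_away(df$f1, 2))
  print(df, row.names = FALSE)
  cat(sprintf("accuracy %.2f | weighted P %.2f R %.2f F1 %.2f\n",
              round_half_away(x$accuracy, 2),
              round_half_away(x$weighted$precision, 2),
              round_half_away(x$weighted$recall, 2),
              round_half_away(x$weighted$f1, 2)))
  invisible(x)
}

#' Two-sample t test on per-video accuracies
#'
#' Pooled-variance (Student) test by default, with degrees of freedom
#' n_a + n_b - 2 (e.g. df 18 when comparing two raters over 10 videos each);
#' Welch available via `pooled = FALSE`. Degenerate inputs are handled
#' explicitly: two lists with zero pooled variance give t = 0, p = 1 when the
#' means agree and an infinite t (p = 0) flagged in `degenerate` otherwise.
#'
#' @param acc_a,acc_b numeric vectors of per-video accuracies (length >= 2)
#' @param pooled use the pooled-variance test (default TRUE)
#' @return list with `t`, `df`, `p`, and `degenerate` flag
#' @export
accuracy_ttest <- function(acc_a, acc_b, pooled = TRUE) {
  if (length(acc_a) < 2 || length(acc_b) < 2)
    stop_input("each accuracy list needs at least 2 values")
  pooled_var <- (sum((acc_a - mean(acc_a))^2) + sum((acc_b - mean(acc_b))^2)) /
    (length(acc_a) + length(acc_b) - 2)
  if (pooled_var == 0) {
    df <- length(acc_a) + length(acc_b) - 2
    if (isTRUE(all.equal(mean(acc_a), mean(acc_b))))
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(acc_a) - mean(acc_b)) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(acc_a, acc_b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Percentage with the package's reporting convention
#'
#' 100 * num / den, rounded half away from zero to one decimal; defined as
#' 0.0 when the denominator is 0.
#'
#' @param num,den numerator and denominator counts
#' @return percentage to one decimal
#' @export
percentage <- function(num, den) {
  if (den == 0) return(0)
  round_half_away(100 * num / den, 1)
}
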