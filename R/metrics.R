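# Confusion-matrix metrics and ROC AUC, reported as percentages to match
# the five-column report layout (accuracy, precision, sensitivity, F1,
# AUC) that the benchmarking harness produces.

#' Confusion counts for binary predictions
#'
#' @param truth Observed binary labels.
#' @param estimate Predicted binary labels, same length.
#' @param positive The label value counted as positive (default 1).
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(truth, estimate, positive = 1) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have the same length", call. = FALSE)
  }
  if (length(truth) < 1L) stop("no observations", call. = FALSE)
  if (length(unique(c(truth, estimate))) > 2L) {
    stop("confusion_counts() handles binary labels only", call. = FALSE)
  }
  t_pos <- truth == positive
  e_pos <- estimate == positive
  tibble::tibble(
    tp = sum(t_pos & e_pos),
    fp = sum(!t_pos & e_pos),
    tn = sum(!t_pos & !e_pos),
    fn = sum(t_pos & !e_pos)
  )
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, sensitivity (TPR) = TP/(TP+FN), precision =
#' TP/(TP+FP), specificity = TN/(TN+FP), and F1 the harmonic mean of
#' precision and sensitivity, all as percentages. Ratios with a zero
#' denominator are reported as 0 with a warning.
#'
#' @param counts A one-row tibble (or list) with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, each in \[0, 100\].
#' @examples
#' confusion_metrics(list(tp = 40, tn = 45, fp = 5, fn = 10))
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  precision <- 100 * safe_ratio(tp, tp + fp, "precision")
  sensitivity <- 100 * safe_ratio(tp, tp + fn, "sensitivity")
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  tibble::tibble(
    accuracy = 100 * (tp + tn) / total,
    precision = precision,
    sensitivity = sensitivity,
    specificity = 100 * safe_ratio(tn, tn + fp, "specificity"),
    f1 = f1
  )
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' The probability that a random positive outranks a random negative,
#' with ties counting one half, as a percentage.
#'
#' @param truth Binary labels; both classes must be present.
#' @param score Real-valued scores, higher meaning more positive.
#' @param positive The positive label value (default 1).
#' @return A number in \[0, 100\].
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))  # 75
#' @export
auc_score <- function(truth, score, positive = 1) {
  if (length(truth) != length(score)) {
    stop("truth and score must have the same length", call. = FALSE)
  }
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(score)  # midranks handle ties as 1/2
  100 * (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
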