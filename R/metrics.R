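#' Multi-class classification report
#'
#' Computes the evaluation suite used throughout the family-classification
#' experiments: overall accuracy, Cohen's kappa (chance-corrected
#' agreement), the multiclass Matthews correlation coefficient (computed
#' from the full confusion matrix), and per-class precision/recall/F1 with
#' macro (unweighted) and weighted (by true-class support) averages.
#' Metrics with a zero denominator are reported as `NA` with a warning
#' rather than silently as 0.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class vocabulary; defaults to the sorted union of labels.
#' @param rejected Optional logical vector marking records rejected by an
#'   uncertainty estimator; metrics are then computed on the accepted
#'   records only and the rejected fraction is reported alongside.
#' @return An object of class `metrics_report`: a list with `accuracy`,
#'   `kappa`, `mcc`, `macro_f1`, `weighted_f1`, the per-class tibble
#'   (`by_class`), the confusion matrix (`confusion`, true classes as rows),
#'   `n`, and `rejected_fraction` (NA when `rejected` is absent).
#'   `glance()` returns the scalar metrics as a one-row tibble; `tidy()` the
#'   per-class table.
#' @examples
#' classification_report(c("a", "a", "b"), c("a", "b", "b"))
#' @export
classification_report <- function(truth, predicted, classes = NULL,
                                  rejected = NULL) {
  if (length(truth) == 0) abort("classification_report requires non-empty input")
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  rejected_fraction <- NA_real_
  if (!is.null(rejected)) {
    rejected_fraction <- mean(rejected)
    truth <- truth[!rejected]
    predicted <- predicted[!rejected]
    if (length(truth) == 0) abort("All records were rejected")
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  if (!all(c(truth, predicted) %in% classes)) {
    abort("Labels outside the supplied class vocabulary")
  }
  C <- length(classes)
  n <- length(truth)
  cm <- table(factor(truth, classes), factor(predicted, classes))
  cm <- matrix(as.numeric(cm), C, C, dimnames = dimnames(cm))
  accuracy <- sum(diag(cm)) / n
  # Cohen's kappa: observed vs chance agreement from the marginals
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) {
    warn("Kappa undefined: chance agreement equals 1"); NA_real_
  } else (accuracy - pe) / (1 - pe)
  # multiclass MCC (correlation form over the confusion matrix)
  tk <- rowSums(cm); pk <- colSums(cm)
  num <- sum(diag(cm)) * n - sum(tk * pk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  mcc <- if (den == 0) {
    warn("MCC undefined: degenerate confusion matrix"); NA_real_
  } else num / den
  tp <- diag(cm)
  prec <- ifelse(pk > 0, tp / pk, NA_real_)
  rec <- ifelse(tk > 0, tp / tk, NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec),
               ifelse(tk + pk > 0, 0, NA_real_))
  if (anyNA(c(prec, rec))) {
    warn("Some per-class metrics are undefined (no true or no predicted samples)")
  }
  by_class <- tibble::tibble(label = classes, support = tk,
                             precision = unname(prec), recall = unname(rec),
                             f1 = unname(f1))
  structure(
    list(accuracy = accuracy, kappa = kappa, mcc = mcc,
         macro_f1 = mean(f1, na.rm = TRUE),
         weighted_f1 = sum(f1 * tk, na.rm = TRUE) /
           sum(tk[!is.na(f1)]),
         by_class = by_class, confusion = cm, n = n,
         rejected_fraction = rejected_fraction),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n = ", x$n,
      if (!is.na(x$rejected_fraction))
        paste0(" (", round(100 * x$rejected_fraction, 2), "% rejected)"),
      "\n  accuracy ", signif(x$accuracy, 4),
      ", kappa ", signif(x$kappa, 4),
      ", MCC ", signif(x$mcc, 4),
      ", macro F1 ", signif(x$macro_f1, 4),
      ", weighted F1 ", signif(x$weighted_f1, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$by_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, kappa = x$kappa, mcc = x$mcc,
                 macro_f1 = x$macro_f1, weighted_f1 = x$weighted_f1,
                 n = x$n, rejected_fraction = x$rejected_fraction)
}

#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$by_class,
                  ggplot2::aes(x = .data$label, y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-class F1") +
    ggplot2::theme_minimal()
}

#' Rank-based ROC-AUC
#'
#' Area under the ROC curve computed by the Mann-Whitney rank statistic:
#' the probability that a random positive scores above a random negative,
#' ties counting one half. Used to evaluate how well an uncertainty score
#' separates functional sequences (label 1, scored so that larger = more
#' functional, e.g. `-H` or `D`) from shuffled negatives (label 0).
#'
#' @param scores Numeric scores, larger meaning more functional.
#' @param labels Binary labels (1/TRUE = functional); both classes required.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)) # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("roc_auc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
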