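# Classification metrics at a probability threshold, plus ROC/AUC.

# Concordance-probability AUC: the probability that a random positive
# outscores a random negative, with ties counted one half. Computed by
# the rank formula, which is exactly the tie-adjusted concordance.
auc_concordance <- function(scores, labels) {
  pos <- labels == 1
  n1 <- as.numeric(sum(pos)); n0 <- as.numeric(sum(!pos))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC step points over the distinct score thresholds, from (0,0) to (1,1).
roc_curve_points <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  keep <- c(diff(s) != 0, TRUE)   # last index within each tied block
  tpr <- cumsum(y)[keep] / n1
  fpr <- cumsum(!y)[keep] / n0
  tibble(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Compute classification metrics at a threshold
#'
#' A prediction is positive iff its probability is greater than or equal
#' to `threshold`. Ratios with a zero denominator (e.g. PPV with no
#' predicted positives) are reported as `NA` and named in the
#' `undefined` field -- never silently zero. The AUC is the concordance
#' probability (random positive outscores random negative, ties one
#' half), which equals the trapezoidal area under the ROC step curve.
#'
#' @param probabilities Numeric vector of predicted probabilities.
#' @param labels Binary ground-truth labels (0/1), aligned.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `"metrics_report"`: confusion counts
#'   (`tp`, `fp`, `fn`, `tn`), `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `f1`, `auc`, a `roc_points` tibble, `threshold`, `n` and the
#'   `undefined` metric names.
#' @export
compute_metrics <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) == 0L) {
    stop("cannot compute metrics on empty input", call. = FALSE)
  }
  stopifnot(length(probabilities) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  n <- length(labels)
  undefined <- character()
  safe_div <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  ppv <- safe_div(tp, tp + fp, "ppv")
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn, "f1")
  single_class <- length(unique(labels)) < 2L
  auc <- if (single_class) {
    undefined <- c(undefined, "auc")
    NA_real_
  } else {
    auc_concordance(probabilities, labels)
  }
  roc <- if (single_class) {
    tibble(fpr = numeric(), tpr = numeric())
  } else {
    roc_curve_points(probabilities, labels)
  }
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec,
    ppv = ppv, f1 = f1, auc = auc, roc_points = roc,
    threshold = threshold, undefined = undefined
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d @ %.2f | acc %.3f sens %s spec %s ppv %s f1 %s auc %s\n",
    x$n, x$threshold, x$accuracy,
    fmt3(x$sensitivity), fmt3(x$specificity), fmt3(x$ppv), fmt3(x$f1),
    fmt3(x$auc)))
  if (length(x$undefined)) {
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

fmt3 <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
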