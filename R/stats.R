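# Statistical comparisons between correctly and incorrectly classified
# records: Welch's t-test for means (record lengths, invalid-rule
# counts) and a Pearson chi-squared contingency test for predicted
# probability distributions.

#' Welch two-sample t-test
#'
#' Two-tailed, unequal-variance (Welch) t-test with the
#' Welch-Satterthwaite degrees of freedom. The Welch form is the right
#' default here because the compared groups (e.g. correct versus
#' incorrect classifications) typically have very unequal sizes and
#' variances.
#'
#' @param a,b Numeric samples, each of size at least 2, with nonzero
#'   combined variance.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
two_sample_ttest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) <= 0) {
    stop("degenerate samples: zero combined variance", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble(method = "Welch two-sample t-test",
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Pearson chi-squared contingency test
#'
#' Pearson's chi-squared without continuity correction on an r x c count
#' table, after dropping rows and columns that are entirely zero;
#' `df = (r - 1)(c - 1)`.
#'
#' @param table A matrix of non-negative integer counts with at least 2
#'   rows and 2 columns remaining after zero rows/columns are dropped.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
chi_square_contingency <- function(table) {
  m <- as.matrix(table)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("contingency table must contain non-negative integer counts",
         call. = FALSE)
  }
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("contingency table needs at least 2 non-zero rows and columns",
         call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(method = "Pearson chi-squared contingency test",
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Compare predicted-probability distributions of correct vs incorrect
#' classifications
#'
#' Bins both groups into `n_bins` equal-width bins on `[0, 1]`, drops
#' bins empty in both groups, and runs [chi_square_contingency()] on the
#' resulting 2 x bins table. A well-calibrated screen shows a bimodal
#' (confident) distribution for correct classifications and a flatter
#' one for errors; this test quantifies that difference.
#'
#' @param correct,incorrect Predicted probabilities for correctly and
#'   incorrectly classified records; both non-empty.
#' @param n_bins Number of equal-width bins (default 10).
#' @return A list with `result` (the test tibble) and `table` (the
#'   2 x bins count matrix actually tested, for inspection).
#' @export
probability_distribution_comparison <- function(correct, incorrect,
                                                n_bins = 10L) {
  n_bins <- assert_count(n_bins, "n_bins", min = 2L)
  if (length(correct) == 0L || length(incorrect) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  assert_probability(c(correct, incorrect), "probabilities")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- function(p) table(cut(p, breaks = breaks, include.lowest = TRUE))
  tab <- rbind(correct = as.integer(bin(correct)),
               incorrect = as.integer(bin(incorrect)))
  colnames(tab) <- levels(cut(numeric(), breaks = breaks, include.lowest = TRUE))
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2L) {
    stop("fewer than 2 usable probability bins", call. = FALSE)
  }
  list(result = chi_square_contingency(tab), table = tab)
}
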