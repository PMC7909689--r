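# Interpretation: gradient saliency-frequency maps for bag-of-words
# models, leave-one-out rule ablation, and the frozen-encoder audit of a
# shifted external corpus.

#' Word saliency for a single record
#'
#' Saliency of a word is the magnitude of the gradient of the predicted
#' positive-class probability with respect to that word's input feature,
#' evaluated at the record's encoding. Only words actually present in
#' the record (nonzero feature) are reported: saliency asks how changing
#' a word *in the corpus* would move the classification.
#'
#' @param model A `"trained_mlp"` trained on bag-of-words features.
#' @param features The record's feature vector (length = vocabulary) or
#'   a one-row matrix.
#' @param vocabulary Character vector naming the feature columns.
#' @return A tibble (`word`, `feature`, `saliency`) sorted by decreasing
#'   saliency, ties alphabetical.
#' @export
word_saliency <- function(model, features, vocabulary) {
  x <- matrix(as.numeric(features), nrow = 1L)
  if (ncol(x) != length(vocabulary)) {
    stop("feature width does not match vocabulary length", call. = FALSE)
  }
  g <- abs(as.vector(input_gradient(model, x)))
  present <- which(x[1L, ] != 0)
  out <- tibble(word = vocabulary[present],
                feature = x[1L, present],
                saliency = g[present])
  out[order(-out$saliency, out$word), ]
}

#' Saliency-frequency map over a test set
#'
#' For each test record, the `k` most salient present words are selected
#' (ties alphabetical; records with fewer than `k` present words
#' contribute what they have). Word occurrences are then counted across
#' records grouped by ground-truth label, and the 50 most frequent words
#' per class are reported. Recurrently salient words reveal what the
#' network keys on for each class.
#'
#' @param model A `"trained_mlp"` trained on bag-of-words features.
#' @param features Feature matrix for the test records.
#' @param labels Ground-truth binary labels (0/1), aligned.
#' @param vocabulary Character vector naming the feature columns.
#' @param k Salient words kept per record (default 50).
#' @param top_n Words reported per class (default 50).
#' @return An object of class `"saliency_report"`: `per_record` (list of
#'   character vectors), `frequencies` (tibble `class`, `word`, `n`) and
#'   `top` (the `top_n` most frequent per class).
#' @export
saliency_frequency_map <- function(model, features, labels, vocabulary,
                                   k = 50L, top_n = 50L) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("empty test set", call. = FALSE)
  stopifnot(nrow(features) == length(labels),
            ncol(features) == length(vocabulary))
  k <- assert_count(k, "k", min = 1L)
  g <- abs(input_gradient(model, features))
  per_record <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    present <- which(features[i, ] != 0)
    if (length(present) == 0L) {
      per_record[[i]] <- character()
      next
    }
    w <- vocabulary[present]
    s <- g[i, present]
    ord <- order(-s, w)
    per_record[[i]] <- w[ord[seq_len(min(k, length(w)))]]
  }
  cls <- ifelse(labels == 1L, "positive", "negative")
  freq <- tibble(
    class = rep(cls, lengths(per_record)),
    word = unlist(per_record, use.names = FALSE)) |>
    dplyr::count(.data$class, .data$word, name = "n") |>
    arrange(.data$class, desc(.data$n), .data$word)
  top <- freq |>
    group_by(.data$class) |>
    slice(seq_len(min(top_n, dplyr::n()))) |>
    ungroup()
  structure(list(per_record = per_record, frequencies = freq, top = top,
                 k = k, top_n = top_n),
            class = "saliency_report")
}

#' @export
print.saliency_report <- function(x, ...) {
  cat(sprintf("<saliency_report> %d records, top %d words per record\n",
              length(x$per_record), x$k))
  invisible(x)
}

#' Leave-one-out rule ablation
#'
#' Invalidates each rule in turn -- setting its column to -1 ("phrase
#' not found") for every test record -- and records the change in
#' accuracy at the given threshold. Model weights are untouched; this is
#' an inference-time sensitivity analysis. Rules whose invalidation does
#' not change accuracy are listed separately.
#'
#' @param model A trained classifier with a `predict` method returning
#'   probabilities (e.g. `"trained_mlp"`).
#' @param features Rules-encoded test matrix (values in \{-1, 0, 1\},
#'   colnames = rule phrases).
#' @param labels Ground-truth binary labels (0/1), aligned.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `"ablation_report"`: `baseline_accuracy`,
#'   `deltas` (tibble `rule`, `delta` with
#'   `delta = accuracy(invalidated) - baseline`) and `zero_impact`
#'   (alphabetical list of rules with `delta == 0`).
#' @export
rule_loo_sensitivity <- function(model, features, labels, threshold = 0.5) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  rules <- colnames(features) %||% as.character(seq_len(ncol(features)))
  baseline <- accuracy_at(predict(model, features), labels, threshold)
  delta <- numeric(ncol(features))
  for (j in seq_len(ncol(features))) {
    xj <- features
    xj[, j] <- -1
    delta[j] <- accuracy_at(predict(model, xj), labels, threshold) - baseline
  }
  deltas <- tibble(rule = rules, delta = delta)
  structure(list(baseline_accuracy = baseline, deltas = deltas,
                 zero_impact = sort(rules[delta == 0]),
                 threshold = threshold),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  worst <- x$deltas[order(x$deltas$delta), ][1L, ]
  cat(sprintf(
    "<ablation_report> baseline accuracy %.3f; largest drop %s (%+.3f); %d of %d rules have zero impact\n",
    x$baseline_accuracy, worst$rule, worst$delta,
    length(x$zero_impact), nrow(x$deltas)))
  invisible(x)
}

#' Screen an external corpus with a frozen encoder and model
#'
#' Cleans external texts with the package pipeline, keeps those whose
#' cleaned word counts fall inside `length_range`, encodes them with an
#' encoder fitted on internal training data only (a `"tfidf_model"` or a
#' `"rule_lexicon"`), and reports the fraction classified positive at
#' the threshold. Because the external corpus is assumed to contain no
#' true positives, that fraction is a false-positive rate under dataset
#' shift. The per-rule prevalence ratio (external / internal fraction of
#' records containing each phrase) localizes which phrases drive the
#' shift; 0/0 is reported as `NA` (undefined).
#'
#' @param model A trained classifier with a `predict` method.
#' @param encoder The frozen encoder state: a `"tfidf_model"` or a
#'   `"rule_lexicon"`.
#' @param external_texts Character vector of raw texts, or a tibble with
#'   a `text` column (e.g. from [generate_external_corpus()]).
#' @param internal_corpora The internal corpora tibble (from
#'   [build_corpus()]) used for the prevalence denominators.
#' @param lexicon The `"rule_lexicon"` whose phrase prevalences are
#'   audited.
#' @param length_range Interval `c(min, max)` of cleaned word counts to
#'   retain.
#' @param threshold Decision threshold (default 0.5).
#' @param stop_words Stop list for cleaning the external texts.
#' @return An object of class `"external_screen_report"`: `n_screened`,
#'   `positive_rate` and `rule_prevalence` (tibble `rule`,
#'   `external_prevalence`, `internal_prevalence`, `ratio`).
#' @export
external_corpus_screen <- function(model, encoder, external_texts,
                                   internal_corpora, lexicon, length_range,
                                   threshold = 0.5,
                                   stop_words = default_stop_words()) {
  stopifnot(inherits(lexicon, "rule_lexicon"), length(length_range) == 2L)
  texts <- if (is.data.frame(external_texts)) external_texts$text else external_texts
  toks <- clean_tokens(texts, stop_words)
  names(toks) <- if (is.data.frame(external_texts) &&
                     "doc_id" %in% names(external_texts)) {
    as.character(external_texts$doc_id)
  } else {
    as.character(seq_along(toks))
  }
  keep <- lengths(toks) >= length_range[1] & lengths(toks) <= length_range[2]
  toks <- toks[keep]
  if (length(toks) == 0L) {
    stop("no external records fall inside the length range", call. = FALSE)
  }
  feats <- if (inherits(encoder, "tfidf_model")) {
    apply_tfidf(encoder, toks)
  } else if (inherits(encoder, "rule_lexicon")) {
    encode_rules(encoder, toks)
  } else {
    stop("`encoder` must be a tfidf_model or a rule_lexicon", call. = FALSE)
  }
  probs <- predict(model, feats)
  ext_hits <- phrase_present(lexicon, toks)
  int_hits <- phrase_present(lexicon, as_token_list(internal_corpora))
  ext_prev <- colMeans(ext_hits)
  int_prev <- colMeans(int_hits)
  ratio <- ifelse(ext_prev == 0 & int_prev == 0, NA_real_,
                  ext_prev / int_prev)
  structure(list(
    n_screened = length(toks),
    positive_rate = mean(probs >= threshold),
    probabilities = probs,
    rule_prevalence = tibble(rule = lexicon$phrase,
                             external_prevalence = unname(ext_prev),
                             internal_prevalence = unname(int_prev),
                             ratio = unname(ratio)),
    threshold = threshold),
    class = "external_screen_report")
}

#' @export
print.external_screen_report <- function(x, ...) {
  cat(sprintf(
    "<external_screen_report> %d records screened; %.1f%% classified positive at %.2f\n",
    x$n_screened, 100 * x$positive_rate, x$threshold))
  invisible(x)
}
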