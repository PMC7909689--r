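# Bag-of-words TF-IDF encoding. The variant is fixed explicitly so it
# can be checked against a brute-force oracle: for vocabulary word w in
# corpus c,
#   weight(w, c) = tf(w, c) * (ln((1 + N) / (1 + df(w))) + 1)
# followed by L2 row normalization (all-zero rows stay zero). High
# weights go to words frequent in the corpus being encoded but
# infrequent across training corpora.

#' Fit a TF-IDF model on training corpora
#'
#' The vocabulary, document frequencies and document count are computed
#' from the training corpora only; applying the model to unseen corpora
#' never updates them, so there is no train/test leakage through the
#' encoder.
#'
#' @param corpora Training corpora: a tibble with a `tokens` list-column
#'   (as from [build_corpus()]) or a bare list of token vectors.
#' @param max_features Optional cap on vocabulary size. Words are kept by
#'   descending collection frequency (total occurrences across corpora),
#'   ties broken alphabetically.
#' @return A list of class `"tfidf_model"` with fields `vocabulary`
#'   (alphabetical), `document_frequency`, `n_documents` and
#'   `max_features`.
#' @export
fit_tfidf <- function(corpora, max_features = NULL) {
  toks <- as_token_list(corpora)
  if (length(toks) == 0L || all(lengths(toks) == 0L)) {
    stop("cannot fit a TF-IDF model: all corpora are empty", call. = FALSE)
  }
  all_tokens <- unlist(toks, use.names = FALSE)
  coll <- table(all_tokens)
  vocab <- names(coll)
  if (!is.null(max_features)) {
    max_features <- assert_count(max_features, "max_features", min = 1L)
    ord <- order(-as.integer(coll), vocab)
    vocab <- sort(vocab[ord[seq_len(min(max_features, length(vocab)))]])
  } else {
    vocab <- sort(vocab)
  }
  df <- vapply(toks, function(tk) vocab %in% tk, logical(length(vocab)))
  df <- if (is.null(dim(df))) as.integer(df) else as.integer(rowSums(df))
  structure(list(
    vocabulary = vocab,
    document_frequency = stats::setNames(df, vocab),
    n_documents = length(toks),
    max_features = max_features
  ), class = "tfidf_model")
}

#' Encode corpora with a fitted TF-IDF model
#'
#' @param model A `"tfidf_model"` from [fit_tfidf()].
#' @param corpora Corpora in any representation accepted by
#'   [fit_tfidf()]; a single token vector is also accepted.
#' @return A dense numeric matrix, one row per corpus (rownames = ids)
#'   and one column per vocabulary word. Rows are L2-normalized; rows
#'   with no in-vocabulary words are all-zero. Out-of-vocabulary words
#'   are ignored.
#' @export
apply_tfidf <- function(model, corpora) {
  stopifnot(inherits(model, "tfidf_model"))
  toks <- as_token_list(corpora)
  vocab <- model$vocabulary
  idf <- log((1 + model$n_documents) / (1 + model$document_frequency)) + 1
  out <- matrix(0, nrow = length(toks), ncol = length(vocab),
                dimnames = list(names(toks), vocab))
  for (i in seq_along(toks)) {
    tk <- toks[[i]][toks[[i]] %in% vocab]
    if (length(tk) == 0L) next
    tf <- table(tk)
    row <- numeric(length(vocab))
    names(row) <- vocab
    row[names(tf)] <- as.numeric(tf)
    row <- row * idf
    nrm <- sqrt(sum(row^2))
    if (nrm > 0) row <- row / nrm
    out[i, ] <- row
  }
  out
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("<tfidf_model> %d words over %d training documents%s\n",
              length(x$vocabulary), x$n_documents,
              if (is.null(x$max_features)) "" else
                sprintf(" (max_features = %d)", x$max_features)))
  invisible(x)
}
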