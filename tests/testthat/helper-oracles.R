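# Independent oracles and hand-built fixtures. Everything here is
# deliberately naive (loops, direct formulas) so it cannot share a code
# path with the implementation it checks.

# Brute-force TF-IDF of the declared formula:
# tf * (ln((1 + N) / (1 + df)) + 1), then L2 normalization.
brute_tfidf_fit <- function(train_toks, max_features = NULL) {
  counts <- list()
  for (doc in train_toks) {
    for (w in doc) counts[[w]] <- (counts[[w]] %||% 0) + 1
  }
  vocab <- names(counts)
  if (!is.null(max_features) && length(vocab) > max_features) {
    cf <- unlist(counts)
    vocab <- vocab[order(-cf, vocab)][seq_len(max_features)]
  }
  vocab <- sort(vocab)
  df <- sapply(vocab, function(w) {
    sum(vapply(train_toks, function(doc) w %in% doc, logical(1)))
  })
  list(vocab = vocab, df = df, N = length(train_toks))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

brute_tfidf_encode <- function(fit, doc) {
  v <- numeric(length(fit$vocab))
  for (k in seq_along(fit$vocab)) {
    w <- fit$vocab[k]
    tf <- sum(doc == w)
    v[k] <- tf * (log((1 + fit$N) / (1 + fit$df[k])) + 1)
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

# Trapezoidal area under an ROC step curve (independent of the rank
# formula used by the package).
trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Central finite-difference gradient of the predicted probability.
fd_gradient <- function(model, x, h = 1e-4) {
  x <- as.numeric(x)
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    g[k] <- (predict(model, matrix(xp, 1)) - predict(model, matrix(xm, 1))) /
      (2 * h)
  }
  g
}

# Hand-built "trained" network computing sigmoid(w . x + c) on the
# region where w . x > -shift (ReLU pass-through trick).
manual_linear_model <- function(w, c0, shift = 100) {
  weights <- list(
    list(W = matrix(w, ncol = 1), b = shift),
    list(W = matrix(1, 1, 1), b = c0 - shift))
  notescreen:::new_trained_mlp(
    weights, mlp_spec(hidden = 1L), mlp_control(epochs = 1L),
    best_epoch = 1L,
    history = tibble::tibble(epoch = 1L, train_loss = NA_real_,
                             train_accuracy = NA_real_, val_loss = NA_real_,
                             val_accuracy = NA_real_),
    val_idx = integer(), input_dim = length(w))
}

# Hand-built rules toy: outputs 0.9 iff feature `j` equals 1, else 0.1.
manual_rule_model <- function(n_rules, j = 1L) {
  w1 <- matrix(0, n_rules, 1)
  w1[j, 1] <- 1
  span <- stats::qlogis(0.9) - stats::qlogis(0.1)
  weights <- list(
    list(W = w1, b = 0),
    list(W = matrix(span, 1, 1), b = stats::qlogis(0.1)))
  notescreen:::new_trained_mlp(
    weights, mlp_spec(hidden = 1L), mlp_control(epochs = 1L),
    best_epoch = 1L,
    history = tibble::tibble(epoch = 1L, train_loss = NA_real_,
                             train_accuracy = NA_real_, val_loss = NA_real_,
                             val_accuracy = NA_real_),
    val_idx = integer(), input_dim = n_rules)
}

# Small random token corpora over a fixed alphabet.
random_corpora <- function(n_docs, max_words, alphabet, allow_empty = FALSE) {
  lapply(seq_len(n_docs), function(i) {
    lo <- if (allow_empty) 0L else 1L
    n <- sample(lo:max_words, 1L)
    if (n == 0L) character() else sample(alphabet, n, replace = TRUE)
  })
}

# A quickly trained small network on random continuous features, for
# gradient checks.
random_trained_net <- function(seed, d = 5L, hidden = c(6L, 4L)) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(40 * d), 40, d)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    train_mlp(x, y, mlp_spec(hidden = hidden),
              mlp_control(epochs = 3L, seed = seed))
  })
}

# Small strong-signal cohort configuration shared across tests: a single
# indicator phrase present in 90% of positives and 10% of negatives.
strong_signal_config <- function(n_patients, seed,
                                 prevalence = 0.55,
                                 phrase_location = "pre_cap",
                                 corpus_words = c(meanlog = log(6000),
                                                  sdlog = 0.6)) {
  cohort_config(
    n_patients = n_patients,
    lexicon = generate_lexicon(1, 0, seed = 101),
    prevalence = prevalence,
    p_present_pos = 0.9, p_present_neg = 0.1,
    phrase_location = phrase_location,
    corpus_words = corpus_words,
    seed = seed)
}

# Generate -> truncate -> clean -> filter, returning retained corpora.
run_preprocess <- function(config) {
  cohort <- generate_cohort(config)
  cohort$notes |>
    truncate_at_cap() |>
    build_corpus() |>
    filter_cohort()
}
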