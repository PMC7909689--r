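# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic integer mixing for derived seeds. Keeps everything inside
# 2^31 - 1 so the result is always a valid R integer seed.
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  x <- 104729
  for (p in parts) {
    x <- (x * 7919 + (abs(p) %% 2147483647)) %% 2147483647
  }
  as.integer(x)
}

# Deterministic seed derived from a word (used for out-of-vocabulary
# embedding vectors keyed by (word, oov_seed)).
string_seed <- function(word, seed) {
  x <- as.numeric(abs(seed) %% 2147483647)
  for (ch in utf8ToInt(word)) {
    x <- (x * 257 + ch) %% 2147483647
  }
  as.integer(x)
}

# Index -> lowercase letter code ("aaa", "aab", ...), used to mint
# synthetic vocabularies that survive the cleaning pipeline (alphabetic,
# multi-character, never stop words).
int_to_letters <- function(i, width = 3L) {
  vapply(i, function(k) {
    k <- k - 1L
    out <- character(width)
    for (pos in seq_len(width)) {
      out[width - pos + 1L] <- letters[(k %% 26L) + 1L]
      k <- k %/% 26L
    }
    paste(out, collapse = "")
  }, character(1))
}

assert_probability <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, what, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", what, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Extract a list of token vectors from the various corpus representations
# accepted by the encoders (a corpora tibble with a `tokens` list-column,
# a bare list of character vectors, or a single character vector).
as_token_list <- function(corpora) {
  if (is.data.frame(corpora)) {
    if (!"tokens" %in% names(corpora)) {
      stop("corpora data frame must have a `tokens` list-column",
           call. = FALSE)
    }
    toks <- corpora$tokens
    ids <- if ("patient_id" %in% names(corpora)) {
      as.character(corpora$patient_id)
    } else if ("doc_id" %in% names(corpora)) {
      as.character(corpora$doc_id)
    } else {
      as.character(seq_along(toks))
    }
    names(toks) <- ids
    return(toks)
  }
  if (is.list(corpora)) {
    if (is.null(names(corpora))) names(corpora) <- as.character(seq_along(corpora))
    return(corpora)
  }
  if (is.character(corpora)) {
    return(stats::setNames(list(corpora), "1"))
  }
  stop("unsupported corpus representation", call. = FALSE)
}
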