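# Word-embedding encoding: a loader for word2vec-style text tables and a
# pooled document encoder. Out-of-vocabulary words receive deterministic
# pseudo-random vectors keyed by (word, oov_seed) so repeated runs are
# reproducible.

#' Load a word-embedding table from word2vec text format
#'
#' Each line is a word followed by `n` reals; an optional first header
#' line may carry the vocabulary size and dimension. Duplicate words keep
#' their first occurrence (with a warning).
#'
#' @param path Path to the embedding file.
#' @param oov_seed Integer seed keying the deterministic random vectors
#'   assigned to out-of-vocabulary words.
#' @return A list of class `"embedding_table"` with fields `dimension`,
#'   `vectors` (matrix, rownames = words) and `oov_seed`.
#' @export
load_embedding <- function(path, oov_seed = 0L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("embedding file is empty", call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  first <- fields[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    fields <- fields[-1L]  # count/dimension header
    if (length(fields) == 0L) stop("embedding file is empty", call. = FALSE)
  }
  n_fields <- lengths(fields)
  dim_n <- n_fields[1L] - 1L
  if (dim_n < 1L || any(n_fields != n_fields[1L])) {
    stop("malformed embedding file: inconsistent vector dimensions",
         call. = FALSE)
  }
  words <- vapply(fields, `[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(dim_n)))
  if (anyNA(vals)) {
    stop("malformed embedding file: non-numeric vector components",
         call. = FALSE)
  }
  mat <- if (dim_n == 1L) matrix(vals, ncol = 1L) else t(vals)
  dup <- duplicated(words)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate embedding entr%s (first kept): %s",
                    sum(dup), if (sum(dup) == 1L) "y" else "ies",
                    paste(unique(words[dup]), collapse = ", ")))
    mat <- mat[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  rownames(mat) <- words
  structure(list(dimension = dim_n, vectors = mat,
                 oov_seed = as.integer(oov_seed)),
            class = "embedding_table")
}

oov_vector <- function(word, dim_n, oov_seed) {
  withr::with_seed(string_seed(word, oov_seed),
                   runif(dim_n, -0.5 / dim_n, 0.5 / dim_n))
}

#' Encode corpora with a word-embedding table
#'
#' Each token maps to its stored vector, or -- for out-of-vocabulary
#' tokens -- to a deterministic pseudo-random vector keyed by
#' `(word, oov_seed)`. The document vector pools token vectors by
#' arithmetic mean (or sum). Coverage is the fraction of tokens found in
#' the table; embeddings trained on unrepresentative corpora show up as
#' low coverage, which is exactly the failure mode that cripples this
#' encoding in practice.
#'
#' @param embedding An `"embedding_table"` from [load_embedding()].
#' @param corpora Corpora in any representation accepted by
#'   [fit_tfidf()].
#' @param pooling `"mean"` (default) or `"sum"`.
#' @return A list with `features` (matrix, one row per corpus) and
#'   `coverage` (named numeric vector). Empty corpora get a zero vector
#'   and coverage 0, with a warning.
#' @export
encode_embedding <- function(embedding, corpora, pooling = c("mean", "sum")) {
  stopifnot(inherits(embedding, "embedding_table"))
  pooling <- match.arg(pooling)
  toks <- as_token_list(corpora)
  dim_n <- embedding$dimension
  known <- rownames(embedding$vectors)
  oov_cache <- new.env(parent = emptyenv())
  feats <- matrix(0, nrow = length(toks), ncol = dim_n,
                  dimnames = list(names(toks), NULL))
  coverage <- stats::setNames(numeric(length(toks)), names(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) == 0L) {
      warning(sprintf("corpus %s is empty: zero vector, coverage 0",
                      names(toks)[i] %||% i))
      next
    }
    hit <- tk %in% known
    coverage[i] <- mean(hit)
    acc <- numeric(dim_n)
    if (any(hit)) {
      tf <- base::table(tk[hit])
      acc <- acc + as.vector(as.numeric(tf) %*%
                               embedding$vectors[names(tf), , drop = FALSE])
    }
    for (w in tk[!hit]) {
      v <- get0(w, envir = oov_cache)
      if (is.null(v)) {
        v <- oov_vector(w, dim_n, embedding$oov_seed)
        assign(w, v, envir = oov_cache)
      }
      acc <- acc + v
    }
    feats[i, ] <- if (pooling == "mean") acc / length(tk) else acc
  }
  list(features = feats, coverage = coverage)
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words, dimension %d (oov_seed %d)\n",
              nrow(x$vectors), x$dimension, x$oov_seed))
  invisible(x)
}
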