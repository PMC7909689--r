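# Rule lexicons: polarized phrase lists in the style of the 88-phrase
# clinician lexicon, plus a synthetic generator used by the simulation
# study (the clinical lexicon itself was never published in full).

#' Construct a rule lexicon
#'
#' @param phrase Character vector of phrases (each a space-separated run
#'   of cleaned tokens).
#' @param polarity Character vector, `"positive"` (phrase indicates
#'   concern for abuse) or `"negative"` (phrase indicates reassurance).
#' @param clean If `TRUE` (default), phrases are passed through
#'   [clean_tokens()] so that matching happens in the same token space as
#'   the corpora (e.g. "History of domestic violence." becomes
#'   "history domestic violence").
#' @param stop_words Stop list used when cleaning phrases; must match
#'   the one used to clean the corpora.
#' @return A tibble of class `"rule_lexicon"` with columns `phrase` and
#'   `polarity`.
#' @export
rule_lexicon <- function(phrase, polarity, clean = TRUE,
                         stop_words = default_stop_words()) {
  polarity <- match.arg(as.character(polarity), c("positive", "negative"),
                        several.ok = TRUE)
  if (length(polarity) == 1L) polarity <- rep(polarity, length(phrase))
  stopifnot(length(phrase) == length(polarity))
  if (clean) {
    phrase <- vapply(clean_tokens(phrase, stop_words = stop_words),
                     paste, character(1), collapse = " ")
  }
  if (any(!nzchar(phrase))) {
    stop("lexicon phrases must be non-empty after cleaning", call. = FALSE)
  }
  if (anyDuplicated(phrase)) {
    stop("lexicon phrases must be distinct after cleaning", call. = FALSE)
  }
  if (length(phrase) < 1L) stop("a lexicon needs at least one phrase", call. = FALSE)
  out <- tibble(phrase = as.character(phrase), polarity = polarity)
  class(out) <- c("rule_lexicon", class(out))
  out
}

#' Generate a synthetic rule lexicon
#'
#' Mints `n_positive + n_negative` distinct multi-token phrases from a
#' reserved token pool (tokens prefixed `"rb"`) that cannot collide with
#' the synthetic background vocabulary (prefixed `"bkg"`), the leakage
#' marker, or any stop word. Positive-concern phrases deliberately
#' outnumber negative ones in realistic configurations, because the
#' absence of a finding is rarely charted.
#'
#' @param n_positive Number of positive-polarity phrases (>= 1).
#' @param n_negative Number of negative-polarity phrases (>= 0).
#' @param seed Integer seed; identical seeds give byte-identical lexicons.
#' @param phrase_lengths Candidate phrase lengths in tokens (default 2:3).
#' @return A `"rule_lexicon"` tibble.
#' @examples
#' generate_lexicon(3, 1, seed = 1)
#' @export
generate_lexicon <- function(n_positive, n_negative, seed,
                             phrase_lengths = 2:3) {
  if (length(n_positive) != 1L || length(n_negative) != 1L ||
      !is.finite(n_positive) || !is.finite(n_negative) ||
      n_positive < 1 || n_negative < 0 ||
      n_positive != round(n_positive) || n_negative != round(n_negative)) {
    stop("`n_positive` must be >= 1 and `n_negative` >= 0", call. = FALSE)
  }
  n_total <- as.integer(n_positive + n_negative)
  withr::local_seed(as.integer(seed))
  lens <- sample(phrase_lengths, n_total, replace = TRUE)
  pool <- paste0("rb", int_to_letters(seq_len(sum(lens)), width = 3L))
  pool <- sample(pool)
  stops <- cumsum(lens)
  starts <- c(1L, head(stops, -1L) + 1L)
  phrases <- vapply(seq_len(n_total), function(k) {
    paste(pool[starts[k]:stops[k]], collapse = " ")
  }, character(1))
  rule_lexicon(
    phrase = phrases,
    polarity = rep(c("positive", "negative"), c(n_positive, n_negative)),
    clean = FALSE
  )
}

#' Read / write a lexicon as two-column TSV
#'
#' The on-disk format is a headerless two-column TSV: phrase, then
#' polarity coded `pos` or `neg`.
#'
#' @param path File path.
#' @return `read_lexicon_tsv()` returns a `"rule_lexicon"`;
#'   `write_lexicon_tsv()` returns `path` invisibly.
#' @export
read_lexicon_tsv <- function(path) {
  df <- readr::read_tsv(path, col_names = c("phrase", "polarity"),
                        col_types = "cc", progress = FALSE)
  pol <- dplyr::recode(df$polarity, pos = "positive", neg = "negative")
  rule_lexicon(df$phrase, pol, clean = TRUE)
}

#' @rdname read_lexicon_tsv
#' @param lexicon A `"rule_lexicon"`.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "rule_lexicon"))
  df <- tibble(phrase = lexicon$phrase,
               polarity = ifelse(lexicon$polarity == "positive", "pos", "neg"))
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
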