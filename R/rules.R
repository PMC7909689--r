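# Rules-based encoding: the polarized 1/0/-1 phrase scheme. A phrase
# must occur as a contiguous run of cleaned tokens; -1 marks "phrase not
# found", so an inapplicable rule does not masquerade as reassurance.

phrase_present <- function(lexicon, toks) {
  # Contiguous-run matching: join tokens with single spaces and search
  # for " phrase " with fixed strings; tokens never contain spaces.
  hay <- paste0(" ", vapply(toks, paste, character(1), collapse = " "), " ")
  needles <- paste0(" ", lexicon$phrase, " ")
  out <- matrix(FALSE, nrow = length(toks), ncol = nrow(lexicon),
                dimnames = list(names(toks), lexicon$phrase))
  for (j in seq_along(needles)) {
    out[, j] <- grepl(needles[j], hay, fixed = TRUE)
  }
  out
}

#' Encode corpora with a rule lexicon (1 / 0 / -1)
#'
#' Rule `j` scores 1 when a positive-polarity phrase occurs as a
#' contiguous token run in the corpus, 0 when a negative-polarity phrase
#' occurs, and -1 when the phrase does not occur at all. Lexicon phrases
#' are assumed to be pre-cleaned with the same pipeline as the corpora
#' ([rule_lexicon()] and [read_lexicon_tsv()] do this on construction).
#'
#' @param lexicon A `"rule_lexicon"`.
#' @param corpora Corpora in any representation accepted by
#'   [fit_tfidf()]; an empty corpus scores -1 on every rule.
#' @return An integer matrix over \{-1, 0, 1\}, one row per corpus, one
#'   column per rule (colnames = phrases).
#' @export
encode_rules <- function(lexicon, corpora) {
  stopifnot(inherits(lexicon, "rule_lexicon"))
  toks <- as_token_list(corpora)
  hits <- phrase_present(lexicon, toks)
  present_value <- ifelse(lexicon$polarity == "positive", 1L, 0L)
  out <- matrix(rep(present_value, each = length(toks)),
                nrow = length(toks),
                dimnames = dimnames(hits))
  out[!hits] <- -1L
  storage.mode(out) <- "integer"
  out
}
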