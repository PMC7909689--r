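# The standard NLTK English stop list (179 entries). Contraction forms
# never survive tokenization (punctuation is stripped first), but the full
# list is kept so a caller comparing against NLTK sees the same set.
nltk_english_stopwords <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "you're", "you've", "you'll", "you'd", "your", "yours", "yourself",
  "yourselves", "he", "him", "his", "himself", "she", "she's", "her",
  "hers", "herself", "it", "it's", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom",
  "this", "that", "that'll", "these", "those", "am", "is", "are", "was",
  "were", "be", "been", "being", "have", "has", "had", "having", "do",
  "does", "did", "doing", "a", "an", "the", "and", "but", "if", "or",
  "because", "as", "until", "while", "of", "at", "by", "for", "with",
  "about", "against", "between", "into", "through", "during", "before",
  "after", "above", "below", "to", "from", "up", "down", "in", "out",
  "on", "off", "over", "under", "again", "further", "then", "once",
  "here", "there", "when", "where", "why", "how", "all", "any", "both",
  "each", "few", "more", "most", "other", "some", "such", "no", "nor",
  "not", "only", "own", "same", "so", "than", "too", "very", "s", "t",
  "can", "will", "just", "don", "don't", "should", "should've", "now",
  "d", "ll", "m", "o", "re", "ve", "y", "ain", "aren", "aren't",
  "couldn", "couldn't", "didn", "didn't", "doesn", "doesn't", "hadn",
  "hadn't", "hasn", "hasn't", "haven", "haven't", "isn", "isn't", "ma",
  "mightn", "mightn't", "mustn", "mustn't", "needn", "needn't", "shan",
  "shan't", "shouldn", "shouldn't", "wasn", "wasn't", "weren", "weren't",
  "won", "won't", "wouldn", "wouldn't"
)

#' Default stop list for note cleaning
#'
#' The NLTK English stop list with the negation words `no`, `not` and
#' `nor` retained by default. Negations carry clinical meaning ("no acute
#' distress" versus "acute distress"), and saliency analyses of
#' bag-of-words abuse classifiers consistently find "no" among the most
#' influential words -- dropping it would blind the models to the single
#' most common way clinicians negate a finding.
#'
#' @param keep_negations If `TRUE` (default), remove `no`, `not` and `nor`
#'   from the stop list so they survive cleaning.
#' @return A character vector of stop words.
#' @examples
#' "no" %in% default_stop_words()        # FALSE: negations are kept
#' "no" %in% default_stop_words(FALSE)   # TRUE: the raw NLTK list
#' @export
default_stop_words <- function(keep_negations = TRUE) {
  if (keep_negations) {
    setdiff(nltk_english_stopwords, c("no", "not", "nor"))
  } else {
    nltk_english_stopwords
  }
}
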