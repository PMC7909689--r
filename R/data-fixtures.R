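#' Starter rule lexicon (synthetic fixture)
#'
#' Returns the path to, or the parsed contents of, the small starter
#' lexicon shipped with the package. This is a *synthetic starter
#' fixture*: the full clinician-curated 88-phrase lexicon used in
#' published screening work was never released, so this file contains
#' only a handful of indicator phrases of the kind clinicians flag
#' (fracture patterns, mechanism consistency, social-history markers),
#' with polarities assigned by the package authors. It exists to
#' exercise the rules-based encoding end to end, not to screen real
#' records.
#'
#' @param parsed If `TRUE` (default), return the parsed
#'   `"rule_lexicon"`; otherwise return the file path.
#' @return A `"rule_lexicon"` or a path.
#' @export
starter_lexicon <- function(parsed = TRUE) {
  path <- system.file("extdata", "starter_lexicon.tsv",
                      package = "notescreen", mustWork = TRUE)
  if (parsed) read_lexicon_tsv(path) else path
}
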