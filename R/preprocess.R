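# Preprocessing: truncation at the first CAP-team note, cleaning, and the
# cohort exclusion filters.

#' Clean free text into word tokens
#'
#' Applies the fixed cleaning pipeline used throughout the package:
#' every punctuation character is replaced by a space, whitespace is
#' collapsed, text is lowercased and split on spaces, then tokens that
#' contain a digit, single-character tokens, and stop-list tokens are
#' dropped, in that order. "Contains a digit" deliberately removes mixed
#' tokens such as `"10mg"` or `"3am"`, so numeric fragments can never
#' leak into a vocabulary. Cleaning is idempotent: running it on already
#' clean tokens returns them unchanged.
#'
#' @param text A character vector of raw texts.
#' @param stop_words Character vector of stop words
#'   (default [default_stop_words()]).
#' @return A list with one character vector of tokens per input text.
#' @examples
#' clean_tokens("Pt. seen at 3 AM, no acute distress.")
#' @export
clean_tokens <- function(text, stop_words = default_stop_words()) {
  text <- gsub("[^[:alnum:][:space:]]", " ", as.character(text))
  text <- tolower(trimws(gsub("[[:space:]]+", " ", text)))
  toks <- strsplit(text, " ", fixed = TRUE)
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!grepl("[0-9]", tk)]
    tk <- tk[nchar(tk) > 1L]
    tk[!tk %in% stop_words]
  })
}

#' Truncate patient records at the first CAP-team note
#'
#' Only the notes written strictly before the first note authored by a
#' member of the child-abuse-pediatrics (CAP) team may inform prediction:
#' everything the CAP team wrote, and everything after it, reflects the
#' specialist work-up the screen is meant to anticipate. This drops, per
#' patient, the first CAP-authored note and all subsequent notes. A
#' patient with no CAP-authored note is returned unchanged.
#'
#' @param notes A notes tibble with columns `patient_id`, `author_role`,
#'   `timestamp` and `text` (plus any others, e.g. `label`), one row per
#'   note, time-ordered within patient.
#' @param cap_roles Character vector of author roles that identify the
#'   CAP team. The default `NULL` treats any role prefixed `"CAP-"`
#'   (e.g. `"CAP-MD"`, `"CAP-NP"`) as a CAP role.
#' @return The notes tibble restricted to pre-CAP notes.
#' @export
truncate_at_cap <- function(notes, cap_roles = NULL) {
  stopifnot(is.data.frame(notes))
  if (nrow(notes) == 0L) return(as_tibble(notes))
  is_cap <- if (is.null(cap_roles)) {
    startsWith(as.character(notes$author_role), "CAP-")
  } else {
    notes$author_role %in% cap_roles
  }
  notes |>
    mutate(.cap = is_cap) |>
    group_by(.data$patient_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    filter(cumsum(.data$.cap) == 0L) |>
    ungroup() |>
    select(-".cap")
}

#' Merge a patient's notes into a cleaned corpus
#'
#' Concatenates each patient's note texts in time order and cleans them
#' with [clean_tokens()]. Expects records that have already been
#' truncated with [truncate_at_cap()]; nothing here re-checks authorship.
#'
#' @param notes A (truncated) notes tibble as in [truncate_at_cap()].
#' @param stop_words Stop list passed to [clean_tokens()].
#' @return A corpora tibble with one row per patient: `patient_id`,
#'   `label` (if present in `notes`, else `NA`), `n_notes`, `tokens`
#'   (list-column of character vectors) and `word_count`. Patients with
#'   zero notes after truncation do not appear; an entirely empty input
#'   yields an empty tibble.
#' @export
build_corpus <- function(notes, stop_words = default_stop_words()) {
  stopifnot(is.data.frame(notes))
  if (nrow(notes) == 0L) {
    return(tibble(patient_id = character(), label = integer(),
                  n_notes = integer(), tokens = list(),
                  word_count = integer()))
  }
  has_label <- "label" %in% names(notes)
  merged <- notes |>
    group_by(.data$patient_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    summarise(
      label = if (has_label) first(.data$label) else NA_integer_,
      n_notes = dplyr::n(),
      text = paste(.data$text, collapse = " "),
      .groups = "drop"
    )
  toks <- clean_tokens(merged$text, stop_words)
  merged |>
    mutate(tokens = toks,
           word_count = lengths(toks)) |>
    select("patient_id", "label", "n_notes", "tokens", "word_count")
}

#' Apply the cohort exclusion filters
#'
#' Excludes records in a fixed order, counting each record once under the
#' first matching rule: (1) unclassified label (`NA`), (2) fewer than
#' `min_notes` notes remaining after truncation, (3) corpus longer than
#' `word_cap` cleaned words, (4) empty corpus. The defaults mirror
#' routine practice for this kind of cohort: at least 2 notes so a
#' "record" is more than a single registration stub, and a 100,000-word
#' cap so one massive chart cannot dominate training memory.
#'
#' @param corpora A corpora tibble from [build_corpus()].
#' @param min_notes Minimum number of notes remaining (default 2).
#' @param word_cap Maximum cleaned word count (default 100000).
#' @return A list of class `"filtered_cohort"` with elements `corpora`
#'   (the retained rows) and `report`, a one-row tibble of class
#'   `"exclusion_report"` whose counts always satisfy
#'   `retained + excluded_* = input records`.
#' @export
filter_cohort <- function(corpora, min_notes = 2L, word_cap = 100000L) {
  stopifnot(is.data.frame(corpora))
  min_notes <- assert_count(min_notes, "min_notes", min = 0L)
  word_cap <- assert_count(word_cap, "word_cap", min = 0L)
  n_in <- nrow(corpora)
  reason <- rep("retained", n_in)
  if (n_in > 0L) {
    unclassified <- is.na(corpora$label)
    few <- !unclassified & corpora$n_notes < min_notes
    over <- !unclassified & !few & corpora$word_count > word_cap
    empty <- !unclassified & !few & !over & corpora$word_count == 0L
    reason[unclassified] <- "unclassified"
    reason[few] <- "few_notes"
    reason[over] <- "over_cap"
    reason[empty] <- "empty"
  }
  report <- tibble(
    input = n_in,
    retained = sum(reason == "retained"),
    excluded_unclassified = sum(reason == "unclassified"),
    excluded_few_notes = sum(reason == "few_notes"),
    excluded_over_cap = sum(reason == "over_cap"),
    excluded_empty = sum(reason == "empty"),
    min_notes = min_notes,
    word_cap = word_cap
  )
  class(report) <- c("exclusion_report", class(report))
  out <- list(corpora = as_tibble(corpora[reason == "retained", , drop = FALSE]),
              report = report)
  class(out) <- "filtered_cohort"
  out
}

#' @export
print.filtered_cohort <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<filtered_cohort> %d of %d records retained (unclassified %d, <%d notes %d, >%d words %d, empty %d)\n",
    r$retained, r$input, r$excluded_unclassified, r$min_notes,
    r$excluded_few_notes, r$word_cap, r$excluded_over_cap, r$excluded_empty))
  invisible(x)
}
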