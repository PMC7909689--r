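# Plain-text interchange: cohorts as JSONL, corpora as JSONL, exclusion
# reports as JSON, configs as YAML, feature matrices as MatrixMarket
# with a JSON sidecar.

#' Write / read a cohort as JSONL
#'
#' One JSON object per line per patient:
#' `{"id", "label", "notes": [{"role", "timestamp", "text"}]}`; an
#' unclassified label is serialized as `null`.
#'
#' @param notes A notes tibble (`patient_id`, `label`, `author_role`,
#'   `timestamp`, `text`).
#' @param path File path.
#' @return `write_cohort_jsonl()` returns `path` invisibly;
#'   `read_cohort_jsonl()` returns a notes tibble.
#' @export
write_cohort_jsonl <- function(notes, path) {
  stopifnot(is.data.frame(notes))
  ids <- unique(notes$patient_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in ids) {
    sub <- notes[notes$patient_id == id, , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    obj <- list(
      id = id,
      label = if (is.na(sub$label[1L])) NULL else unname(sub$label[1L]),
      notes = lapply(seq_len(nrow(sub)), function(i) list(
        role = sub$author_role[i], timestamp = sub$timestamp[i],
        text = sub$text[i])))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyDataFrame = FALSE)
    lab <- if (is.null(obj$label)) NA_integer_ else as.integer(obj$label)
    tibble(
      patient_id = obj$id, label = lab,
      note_id = seq_along(obj$notes),
      author_role = vapply(obj$notes, `[[`, character(1), "role"),
      timestamp = vapply(obj$notes, `[[`, character(1), "timestamp"),
      text = vapply(obj$notes, `[[`, character(1), "text"))
  })
  bind_rows(rows)
}

#' Write / read cleaned corpora as JSONL
#'
#' One object per line: `{"id", "label", "tokens": [...]}`.
#'
#' @param corpora A corpora tibble from [build_corpus()].
#' @param path File path.
#' @export
write_corpora_jsonl <- function(corpora, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(corpora))) {
    obj <- list(id = corpora$patient_id[i],
                label = if (is.na(corpora$label[i])) NULL else
                  unname(corpora$label[i]),
                tokens = corpora$tokens[[i]])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_corpora_jsonl
#' @export
read_corpora_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyDataFrame = FALSE)
    toks <- as.character(unlist(obj$tokens))
    tibble(patient_id = obj$id,
           label = if (is.null(obj$label)) NA_integer_ else as.integer(obj$label),
           n_notes = NA_integer_,
           tokens = list(toks),
           word_count = length(toks))
  })
  bind_rows(rows)
}

#' Write an exclusion report as JSON
#'
#' @param report An `"exclusion_report"` (from [filter_cohort()]).
#' @param path File path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(as.list(as.data.frame(report)), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write / read a cohort configuration as YAML
#'
#' The lexicon travels inside the YAML as parallel `phrase`/`polarity`
#' lists; everything else round-trips as plain scalars and vectors.
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  obj <- list(
    n_patients = config$n_patients,
    prevalence = config$prevalence,
    lexicon = list(phrase = config$lexicon$phrase,
                   polarity = config$lexicon$polarity),
    p_present_pos = config$p_present_pos,
    p_present_neg = config$p_present_neg,
    notes_per_patient = as.list(config$notes_per_patient),
    post_notes = as.list(config$post_notes),
    corpus_words = as.list(config$corpus_words),
    background_vocab_size = length(config$background_vocab),
    zipf_exponent = config$zipf_exponent,
    phrase_location = config$phrase_location,
    leakage_token = config$leakage_token,
    seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  lex <- rule_lexicon(obj$lexicon$phrase, obj$lexicon$polarity, clean = FALSE)
  cohort_config(
    n_patients = obj$n_patients, lexicon = lex,
    prevalence = obj$prevalence,
    p_present_pos = unlist(obj$p_present_pos),
    p_present_neg = unlist(obj$p_present_neg),
    notes_per_patient = unlist(obj$notes_per_patient),
    post_notes = unlist(obj$post_notes),
    corpus_words = unlist(obj$corpus_words),
    background_vocab_size = obj$background_vocab_size,
    zipf_exponent = obj$zipf_exponent,
    phrase_location = obj$phrase_location,
    leakage_token = obj$leakage_token,
    seed = obj$seed)
}

#' Persist a feature matrix as MatrixMarket with a JSON sidecar
#'
#' Writes `<stem>.mtx` (sparse MatrixMarket) and `<stem>.json` (row ids
#' and column names), a plain-text pair that survives any toolchain.
#'
#' @param features A numeric matrix with rownames (record ids) and
#'   colnames (feature names).
#' @param stem Path stem (without extension).
#' @export
write_feature_matrix <- function(features, stem) {
  m <- Matrix::Matrix(features, sparse = TRUE)
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  jsonlite::write_json(
    list(row_ids = rownames(features) %||% as.character(seq_len(nrow(features))),
         col_names = colnames(features) %||% as.character(seq_len(ncol(features)))),
    paste0(stem, ".json"))
  invisible(stem)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  side <- jsonlite::fromJSON(paste0(stem, ".json"))
  dimnames(m) <- list(side$row_ids, side$col_names)
  m
}

#' Persist a cross-validation result directory
#'
#' Writes `folds.json` (the row-to-fold table plus the configuration)
#' and `metrics.csv` (one row per trained model) into `dir`.
#'
#' @param cv_result A `"cv_result"`.
#' @param dir Output directory (created if needed).
#' @export
write_cv_result <- function(cv_result, dir) {
  stopifnot(inherits(cv_result, "cv_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(folds = cv_result$folds,
         n_splits = cv_result$cv$n_splits,
         n_repetitions = cv_result$cv$n_repetitions,
         master_seed = cv_result$cv$master_seed),
    file.path(dir, "folds.json"))
  readr::write_csv(
    cv_result$results |>
      select("split", "repetition", "architecture", "accuracy", "auc",
             "n_test", "n_parameters"),
    file.path(dir, "metrics.csv"), progress = FALSE)
  invisible(dir)
}
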