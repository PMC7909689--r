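# Synthetic EMR cohorts. The generator emulates the statistical shape the
# screening analysis assumes -- multi-note records truncated at a
# CAP-team note, class-conditional indicator phrases, heavy-tailed note
# counts and corpus lengths -- without attempting clinically realistic
# prose. It exists so every stage of the pipeline can be verified without
# protected patient data.

#' Configuration for a synthetic cohort
#'
#' @param n_patients Number of patients.
#' @param lexicon A [rule_lexicon()]; per-phrase presence is Bernoulli,
#'   class-conditional, independent across phrases given the class.
#' @param prevalence Probability of a positive (abuse) label; default
#'   0.55, the prevalence reported for the study cohort this generator
#'   stands in for.
#' @param p_present_pos,p_present_neg Per-phrase presence probabilities
#'   in the positive / negative class (recycled if scalar). Defaults:
#'   positive-polarity phrases 0.22 / 0.15, negative-polarity phrases
#'   0.10 / 0.18. Concern phrases are charted somewhat more often in
#'   abuse-positive records and reassurance phrases in negatives, but
#'   each phrase is individually weak; with a full-sized lexicon the
#'   aggregate Bayes-optimal AUC sits near 0.9, the discriminability
#'   scale at which real pre-referral screens operate (see
#'   [bayes_reference_auc()]).
#' @param notes_per_patient Negative-binomial parameters `c(size, mu)`
#'   for the number of pre-CAP notes beyond the guaranteed first one
#'   (heavy right tail, echoing real note-count distributions).
#' @param post_notes Negative-binomial parameters `c(size, mu)` for the
#'   number of notes after the CAP note.
#' @param corpus_words Log-normal parameters `c(meanlog, sdlog)` for the
#'   pre-CAP corpus length in words; the default median is 6000 words,
#'   the order of magnitude of real per-patient merged corpora.
#' @param background_vocab_size Size of the Zipf-distributed background
#'   vocabulary (tokens prefixed `"bkg"`, disjoint from phrase tokens).
#' @param zipf_exponent Zipf exponent for background token frequencies.
#' @param phrase_location `"pre_cap"` (default): indicator phrases are
#'   inserted into pre-CAP notes, where a screen restricted to pre-referral
#'   text can see them. `"post_cap"`: phrases go into the CAP-and-later
#'   notes only, so a correctly truncating pipeline sees pure noise --
#'   the configuration used to audit truncation leakage.
#' @param leakage_token A sentinel token injected into every CAP-or-later
#'   note and nowhere else; any occurrence in a cleaned corpus proves the
#'   truncation leaked.
#' @param seed Integer seed; identical configs (same seed) generate
#'   byte-identical cohorts.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients,
                          lexicon,
                          prevalence = 0.55,
                          p_present_pos = NULL,
                          p_present_neg = NULL,
                          notes_per_patient = c(size = 1.5, mu = 6),
                          post_notes = c(size = 1, mu = 2),
                          corpus_words = c(meanlog = log(6000), sdlog = 0.6),
                          background_vocab_size = 500L,
                          zipf_exponent = 1.1,
                          phrase_location = c("pre_cap", "post_cap"),
                          leakage_token = "capleakmarker",
                          seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients", min = 0L)
  stopifnot(inherits(lexicon, "rule_lexicon"))
  assert_probability(prevalence, "prevalence")
  R <- nrow(lexicon)
  pos_pol <- lexicon$polarity == "positive"
  if (is.null(p_present_pos)) p_present_pos <- ifelse(pos_pol, 0.22, 0.10)
  if (is.null(p_present_neg)) p_present_neg <- ifelse(pos_pol, 0.15, 0.18)
  p_present_pos <- rep_len(p_present_pos, R)
  p_present_neg <- rep_len(p_present_neg, R)
  assert_probability(p_present_pos, "p_present_pos")
  assert_probability(p_present_neg, "p_present_neg")
  phrase_location <- match.arg(phrase_location)
  background_vocab_size <- assert_count(background_vocab_size,
                                        "background_vocab_size", min = 1L)
  stopifnot(zipf_exponent > 0, is.character(leakage_token),
            length(leakage_token) == 1L, nzchar(leakage_token))
  vocab <- paste0("bkg", int_to_letters(seq_len(background_vocab_size)))
  phrase_tokens <- unique(unlist(strsplit(lexicon$phrase, " ", fixed = TRUE)))
  vocab <- setdiff(vocab, c(phrase_tokens, leakage_token))
  structure(list(
    n_patients = n_patients, lexicon = lexicon, prevalence = prevalence,
    p_present_pos = p_present_pos, p_present_neg = p_present_neg,
    notes_per_patient = notes_per_patient, post_notes = post_notes,
    corpus_words = corpus_words, background_vocab = vocab,
    zipf_exponent = zipf_exponent, phrase_location = phrase_location,
    leakage_token = leakage_token, seed = as.integer(seed)
  ), class = "cohort_config")
}

zipf_stream <- function(vocab, n, exponent) {
  if (n <= 0L) return(character())
  w <- seq_along(vocab)^(-exponent)
  vocab[sample.int(length(vocab), n, replace = TRUE, prob = w)]
}

# Replace non-overlapping random slices of `stream` with the given
# phrases (token vectors). Slicing keeps the target length distribution
# intact. The stream is chunked so insertions can never overlap.
insert_phrases <- function(stream, phrase_tokens) {
  k <- length(phrase_tokens)
  if (k == 0L) return(stream)
  L <- length(stream)
  max_m <- max(lengths(phrase_tokens))
  if (L < 2L * k * max_m) {
    stop("stream too short to hold the present phrases", call. = FALSE)
  }
  bounds <- floor(seq(0L, L, length.out = k + 1L))
  order_k <- sample.int(k)
  for (c_idx in seq_len(k)) {
    ph <- phrase_tokens[[order_k[c_idx]]]
    lo <- bounds[c_idx] + 1L
    hi <- bounds[c_idx + 1L]
    m <- length(ph)
    start <- lo + sample.int(hi - lo - m + 2L, 1L) - 1L
    stream[start:(start + m - 1L)] <- ph
  }
  stream
}

split_stream <- function(stream, n_parts) {
  if (n_parts == 1L) return(list(stream))
  sizes <- drop(rmultinom(1L, length(stream), rep(1 / n_parts, n_parts)))
  idx <- rep.int(seq_len(n_parts), sizes)
  out <- split(stream, factor(idx, levels = seq_len(n_parts)))
  unname(out)
}

iso_time <- function(base, offset_hours) {
  format(base + offset_hours * 3600, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Generate a synthetic labeled cohort
#'
#' For each patient: a label is drawn from `Bernoulli(prevalence)`;
#' per-phrase presence indicators are drawn from the class-conditional
#' Bernoulli probabilities; present phrases are inserted verbatim as
#' contiguous token runs into the pre-CAP text (or post-CAP text, under
#' the leakage-audit configuration); background tokens are Zipf-sampled.
#' Every record has at least one pre-CAP note, exactly one CAP-authored
#' note, and zero or more later notes; every CAP-or-later note carries
#' the leakage sentinel token. Timestamps are strictly increasing
#' ISO-8601 instants.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"synthetic_cohort"` with elements `notes`
#'   (tibble: `patient_id`, `label`, `note_id`, `author_role`,
#'   `timestamp`, `text`), `truth` (tibble: `patient_id`, `phrase`,
#'   `present` -- the exact indicators used during generation) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  lex <- config$lexicon
  R <- nrow(lex)
  phrase_tok <- strsplit(lex$phrase, " ", fixed = TRUE)
  max_m <- max(lengths(phrase_tok))
  if (n == 0L) {
    out <- list(
      notes = tibble(patient_id = character(), label = integer(),
                     note_id = integer(), author_role = character(),
                     timestamp = character(), text = character()),
      truth = tibble(patient_id = character(), phrase = character(),
                     present = integer()),
      config = config)
    class(out) <- "synthetic_cohort"
    return(out)
  }
  withr::local_seed(config$seed)
  labels <- rbinom(n, 1L, config$prevalence)
  pmat <- matrix(rep(config$p_present_neg, each = n), nrow = n)
  pmat[labels == 1L, ] <- matrix(rep(config$p_present_pos, each = sum(labels == 1L)),
                                 nrow = sum(labels == 1L))
  x <- matrix(rbinom(n * R, 1L, pmat), nrow = n)
  base_time <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  nb_pre <- config$notes_per_patient
  nb_post <- config$post_notes
  cw <- config$corpus_words
  ids <- sprintf("pt%05d", seq_len(n))
  note_rows <- vector("list", n)
  for (i in seq_len(n)) {
    present <- which(x[i, ] == 1L)
    k <- length(present)
    n_pre <- 1L + rnbinom(1L, size = nb_pre[["size"]], mu = nb_pre[["mu"]])
    total <- max(40L, round(rlnorm(1L, cw[["meanlog"]], cw[["sdlog"]])))
    if (config$phrase_location == "pre_cap" && k > 0L) {
      total <- max(total, 4L * k * max_m)
    }
    pre_stream <- zipf_stream(config$background_vocab, total, config$zipf_exponent)
    if (config$phrase_location == "pre_cap" && k > 0L) {
      pre_stream <- insert_phrases(pre_stream, phrase_tok[present])
    }
    pre_notes <- split_stream(pre_stream, n_pre)
    n_post <- rnbinom(1L, size = nb_post[["size"]], mu = nb_post[["mu"]])
    post_total <- max(40L, round(0.25 * total))
    if (config$phrase_location == "post_cap" && k > 0L) {
      post_total <- max(post_total, 4L * k * max_m)
    }
    post_stream <- zipf_stream(config$background_vocab, post_total,
                               config$zipf_exponent)
    if (config$phrase_location == "post_cap" && k > 0L) {
      post_stream <- insert_phrases(post_stream, phrase_tok[present])
    }
    post_notes <- split_stream(post_stream, 1L + n_post)
    # Each CAP-or-later note carries the leakage sentinel.
    post_notes <- lapply(post_notes, function(tk) {
      pos <- sample.int(length(tk) + 1L, 1L)
      append(tk, config$leakage_token, after = pos - 1L)
    })
    roles <- c(sample(c("RN", "MD", "SW"), n_pre, replace = TRUE),
               sample(c("CAP-MD", "CAP-NP"), 1L),
               if (n_post > 0L)
                 sample(c("RN", "MD", "SW", "CAP-MD", "CAP-NP"), n_post,
                        replace = TRUE))
    texts <- vapply(c(pre_notes, post_notes), paste, character(1),
                    collapse = " ")
    n_notes <- length(texts)
    note_rows[[i]] <- tibble(
      patient_id = ids[i], label = labels[i],
      note_id = seq_len(n_notes), author_role = roles,
      timestamp = iso_time(base_time + (i - 1) * 86400 * 7, seq_len(n_notes)),
      text = texts)
  }
  truth <- tibble(
    patient_id = rep(ids, each = R),
    phrase = rep(lex$phrase, times = n),
    present = as.integer(t(x)))
  out <- list(notes = bind_rows(note_rows), truth = truth, config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- length(unique(x$notes$patient_id))
  cat(sprintf("<synthetic_cohort> %d patients, %d notes, %d lexicon phrases\n",
              n, nrow(x$notes), nrow(x$config$lexicon)))
  invisible(x)
}

#' Generate an unlabeled external corpus under dataset shift
#'
#' Emulates an external audit corpus (in spirit, adult-ICU discharge
#' records screened by a model trained on pediatric charts): documents of
#' controlled length whose per-phrase prevalence follows `shift` rather
#' than the cohort's class-conditional probabilities. Documents are
#' emitted as already-clean token streams, so the cleaned word count of
#' each text falls exactly inside `length_range`.
#'
#' @param config A [cohort_config()] supplying the lexicon and background
#'   vocabulary.
#' @param shift Per-phrase presence probabilities (recycled if scalar).
#' @param length_range Integer interval `c(min, max)` of cleaned word
#'   counts.
#' @param n Number of documents.
#' @param seed Integer seed.
#' @return A tibble with columns `doc_id` and `text`.
#' @export
generate_external_corpus <- function(config, shift, length_range, n, seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- assert_count(n, "n", min = 0L)
  R <- nrow(config$lexicon)
  shift <- rep_len(shift, R)
  assert_probability(shift, "shift")
  if (length(length_range) != 2L || any(!is.finite(length_range)) ||
      length_range[1] > length_range[2] || length_range[1] < 1) {
    stop("`length_range` must be a non-empty interval c(min, max)",
         call. = FALSE)
  }
  if (n == 0L) return(tibble(doc_id = character(), text = character()))
  phrase_tok <- strsplit(config$lexicon$phrase, " ", fixed = TRUE)
  max_m <- max(lengths(phrase_tok))
  if (length_range[1] < 2 * R * max_m) {
    stop("`length_range` too short to hold the lexicon phrases", call. = FALSE)
  }
  withr::local_seed(as.integer(seed))
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  texts <- character(n)
  for (i in seq_len(n)) {
    stream <- zipf_stream(config$background_vocab, lens[i], config$zipf_exponent)
    present <- which(rbinom(R, 1L, shift) == 1L)
    if (length(present) > 0L) {
      stream <- insert_phrases(stream, phrase_tok[present])
    }
    texts[i] <- paste(stream, collapse = " ")
  }
  tibble(doc_id = sprintf("ext%05d", seq_len(n)), text = texts)
}

#' Bayes-optimal reference AUC for a cohort configuration
#'
#' Scores a phrase-presence vector by its exact log-likelihood ratio
#' `sum_j x_j log(p1j/p0j) + (1 - x_j) log((1-p1j)/(1-p0j))` and returns
#' the concordance-probability AUC (ties counted one half) between the
#' class-conditional score distributions. This is the ceiling any
#' classifier operating on the rules-based encoding can reach, so
#' cross-validated AUCs can be judged against it. With two phrases or
#' fewer all `2^R` presence patterns are enumerated exactly; otherwise
#' the AUC is estimated by Monte Carlo with `n_mc` draws per class.
#'
#' @param config A [cohort_config()].
#' @param n_mc Monte-Carlo draws per class (ignored for `R <= 2`).
#' @param seed Integer seed for the Monte-Carlo path.
#' @return A single AUC in `[0.5, 1]`.
#' @export
bayes_reference_auc <- function(config, n_mc = 20000L, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  p1 <- config$p_present_pos
  p0 <- config$p_present_neg
  R <- length(p1)
  if (R < 1L) stop("lexicon is empty", call. = FALSE)
  if (any(p1 %in% c(0, 1)) || any(p0 %in% c(0, 1))) {
    stop("presence probabilities of exactly 0 or 1 give an infinite log-likelihood ratio",
         call. = FALSE)
  }
  w <- log(p1 / p0)
  w0 <- log((1 - p1) / (1 - p0))
  score_of <- function(xmat) as.vector(xmat %*% w + (1 - xmat) %*% w0)
  if (R <= 2L) {
    grid <- as.matrix(expand.grid(rep(list(0:1), R)))
    s <- score_of(grid)
    pr1 <- apply(grid, 1L, function(x) prod(ifelse(x == 1, p1, 1 - p1)))
    pr0 <- apply(grid, 1L, function(x) prod(ifelse(x == 1, p0, 1 - p0)))
    d <- outer(s, s, "-")
    gt <- (d > 1e-12) + 0.5 * (abs(d) <= 1e-12)
    return(as.numeric(pr1 %*% gt %*% pr0))
  }
  n_mc <- assert_count(n_mc, "n_mc", min = 1L)
  withr::local_seed(as.integer(seed))
  x1 <- matrix(rbinom(n_mc * R, 1L, rep(p1, each = n_mc)), nrow = n_mc)
  x0 <- matrix(rbinom(n_mc * R, 1L, rep(p0, each = n_mc)), nrow = n_mc)
  auc_concordance(c(score_of(x1), score_of(x0)),
                  rep(c(1L, 0L), each = n_mc))
}
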