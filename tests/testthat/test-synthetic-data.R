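test_that("generate_lexicon produces distinct polarized multi-token phrases", {
  one <- generate_lexicon(1, 0, seed = 1)
  expect_s3_class(one, "rule_lexicon")
  expect_equal(nrow(one), 1L)
  expect_equal(one$polarity, "positive")

  lex <- generate_lexicon(70, 18, seed = 7)
  expect_equal(nrow(lex), 88L)
  expect_equal(sum(lex$polarity == "positive"), 70L)
  expect_false(anyDuplicated(lex$phrase) > 0)
  expect_true(all(lengths(strsplit(lex$phrase, " ")) >= 2))
  # reserved token pool: phrases can never collide with background vocab
  expect_true(all(startsWith(unlist(strsplit(lex$phrase, " ")), "rb")))

  expect_identical(generate_lexicon(5, 2, seed = 3),
                   generate_lexicon(5, 2, seed = 3))
  expect_error(generate_lexicon(0, 2, seed = 1), "n_positive")
  expect_error(generate_lexicon(3, -1, seed = 1), "n_negative")
})

test_that("cohort labels follow the configured prevalence", {
  cfg <- cohort_config(1000, generate_lexicon(2, 1, seed = 1),
                       prevalence = 0.55, seed = 11,
                       corpus_words = c(meanlog = log(100), sdlog = 0.3))
  cohort <- generate_cohort(cfg)
  n_pos <- cohort$notes |>
    dplyr::distinct(patient_id, label) |>
    dplyr::pull(label) |>
    sum()
  # 3 binomial standard deviations around 550
  expect_gte(n_pos, 503)
  expect_lte(n_pos, 597)
})

test_that("cohort generation is seeded and structurally sound", {
  lex <- generate_lexicon(3, 1, seed = 2)
  cfg <- cohort_config(25, lex, seed = 9,
                       corpus_words = c(meanlog = log(200), sdlog = 0.4))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$notes, b$notes)
  expect_identical(a$truth, b$truth)
  cfg2 <- cohort_config(25, lex, seed = 10,
                        corpus_words = c(meanlog = log(200), sdlog = 0.4))
  expect_false(identical(generate_cohort(cfg2)$notes, a$notes))

  empty <- generate_cohort(cohort_config(0, lex, seed = 1))
  expect_equal(nrow(empty$notes), 0L)
  expect_equal(nrow(empty$truth), 0L)

  # every record: >= 1 pre-CAP note and >= 1 CAP-or-later note
  per <- a$notes |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(n_pre = sum(cumsum(startsWith(author_role, "CAP-")) == 0),
                     n_cap = sum(cumsum(startsWith(author_role, "CAP-")) > 0))
  expect_true(all(per$n_pre >= 1))
  expect_true(all(per$n_cap >= 1))

  # timestamps strictly increasing within patient
  ok <- a$notes |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(ok = !is.unsorted(timestamp, strictly = TRUE)) |>
    dplyr::pull(ok)
  expect_true(all(ok))
})

test_that("leakage token is confined to CAP-and-later notes and truth matches text", {
  lex <- generate_lexicon(4, 2, seed = 5)
  cfg <- cohort_config(40, lex, seed = 21,
                       corpus_words = c(meanlog = log(300), sdlog = 0.4))
  cohort <- generate_cohort(cfg)
  pre <- truncate_at_cap(cohort$notes)
  expect_false(any(grepl(cfg$leakage_token, pre$text, fixed = TRUE)))
  post <- dplyr::anti_join(cohort$notes, pre,
                           by = c("patient_id", "note_id"))
  hits_per_patient <- vapply(
    split(post$text, post$patient_id),
    function(tx) any(grepl(cfg$leakage_token, tx, fixed = TRUE)), logical(1))
  expect_true(all(hits_per_patient))

  # phrase occurs contiguously in the pre-CAP text iff its truth indicator is 1
  merged <- vapply(split(pre$text, pre$patient_id), paste,
                   character(1), collapse = " ")
  for (pid in names(merged)) {
    hay <- paste0(" ", merged[[pid]], " ")
    truth_i <- cohort$truth[cohort$truth$patient_id == pid, ]
    found <- vapply(paste0(" ", truth_i$phrase, " "),
                    function(p) grepl(p, hay, fixed = TRUE), logical(1))
    expect_equal(as.integer(found), truth_i$present, info = pid)
  }
})

test_that("external corpus respects length bounds and shifted prevalence", {
  lex <- generate_lexicon(2, 0, seed = 4)
  cfg <- cohort_config(10, lex, seed = 1)
  expect_equal(nrow(generate_external_corpus(cfg, 0.5, c(50, 60), 0, seed = 1)),
               0L)
  expect_error(generate_external_corpus(cfg, 0.5, c(100, 50), 5, seed = 1),
               "length_range")

  ext <- generate_external_corpus(cfg, 0.5, c(5000, 7000), 50, seed = 3)
  wc <- lengths(clean_tokens(ext$text))
  expect_true(all(wc >= 5000 & wc <= 7000))

  # configured prevalence ratio ~ 0.9 / 0.05 = 18 recovers empirically
  shift <- c(0.9, 0.05)
  big <- generate_external_corpus(cfg, shift, c(150, 200), 3000, seed = 8)
  toks <- clean_tokens(big$text)
  hay <- paste0(" ", vapply(toks, paste, character(1), collapse = " "), " ")
  prev <- vapply(lex$phrase,
                 function(p) mean(grepl(paste0(" ", p, " "), hay, fixed = TRUE)),
                 numeric(1))
  expect_lt(abs(prev[1] / prev[2] - 18), 5)
})

test_that("bayes_reference_auc matches exhaustive enumeration", {
  lex1 <- generate_lexicon(1, 0, seed = 1)
  flat <- cohort_config(10, lex1, p_present_pos = 0.3, p_present_neg = 0.3)
  expect_equal(bayes_reference_auc(flat), 0.5)

  strong <- cohort_config(10, lex1, p_present_pos = 0.9, p_present_neg = 0.1)
  # enumeration: 0.81 concordant + 0.5 * 0.18 ties
  expect_equal(bayes_reference_auc(strong), 0.90)

  lex2 <- generate_lexicon(2, 0, seed = 2)
  two <- cohort_config(10, lex2, p_present_pos = 0.9, p_present_neg = 0.1)
  # hand enumeration over the 16 outcome pairs: P(k1 > k0) = 0.9477,
  # ties 0.0486 -> AUC = 0.9477 + 0.0243 = 0.972
  expect_equal(bayes_reference_auc(two), 0.972, tolerance = 1e-12)
  expect_gt(bayes_reference_auc(two), 0.90)

  expect_error(
    bayes_reference_auc(cohort_config(10, lex1, p_present_pos = 1,
                                      p_present_neg = 0.1)),
    "infinite")
})

test_that("Monte-Carlo bayes reference converges to the enumerated value", {
  lex2 <- generate_lexicon(2, 0, seed = 2)
  two <- cohort_config(10, lex2, p_present_pos = 0.9, p_present_neg = 0.1)
  enumerated <- bayes_reference_auc(two)
  # force the Monte-Carlo path via a 3-phrase config whose third phrase
  # is uninformative, so the exact value is still the enumerated one
  lex3 <- generate_lexicon(3, 0, seed = 3)
  three <- cohort_config(10, lex3, p_present_pos = c(0.9, 0.9, 0.4),
                         p_present_neg = c(0.1, 0.1, 0.4))
  mc <- bayes_reference_auc(three, n_mc = 50000, seed = 42)
  expect_lt(abs(mc - enumerated), 0.005)  # ~3 SE at this sample size
})
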