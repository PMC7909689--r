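toy_corpora <- list(c("rib", "fracture", "rib"),
                    c("bruise", "fracture"),
                    c("bruise", "swelling"))

test_that("fit_tfidf builds vocabulary and document frequencies", {
  m <- fit_tfidf(toy_corpora)
  expect_equal(m$vocabulary, c("bruise", "fracture", "rib", "swelling"))
  expect_equal(unname(m$document_frequency), c(2L, 2L, 1L, 1L))
  expect_equal(m$n_documents, 3L)

  # collection frequencies: bruise 2, fracture 2, rib 2, swelling 1;
  # the three-way tie at 2 is broken alphabetically, dropping rib
  m2 <- fit_tfidf(toy_corpora, max_features = 2)
  expect_equal(m2$vocabulary, c("bruise", "fracture"))

  single <- fit_tfidf(list(c("hematoma")))
  expect_equal(unname(single$document_frequency), 1L)
  expect_equal(single$n_documents, 1L)

  expect_error(fit_tfidf(list(character(), character())), "empty")
})

test_that("apply_tfidf matches the declared formula and normalization", {
  m <- fit_tfidf(toy_corpora)
  v <- apply_tfidf(m, list(c("rib", "fracture", "rib")))[1, ]
  # pre-norm: rib 2 * (ln(4/2) + 1) = 3.3863, fracture 1 * (ln(4/3) + 1)
  expect_equal(unname(v[c("rib", "fracture")]), c(0.93472, 0.35545),
               tolerance = 1e-4)
  expect_equal(unname(v[c("bruise", "swelling")]), c(0, 0))
  expect_equal(sum(v^2), 1, tolerance = 1e-12)

  oov <- apply_tfidf(m, list(c("unseen", "words")))[1, ]
  expect_true(all(oov == 0))
})

test_that("encoding test corpora never mutates a fitted TF-IDF model", {
  m <- fit_tfidf(toy_corpora)
  before <- unclass(m)
  invisible(apply_tfidf(m, list(c("new", "unseen", "bruise"))))
  expect_identical(unclass(m), before)
})

test_that("apply_tfidf agrees with a brute-force oracle on random corpora", {
  alphabet <- paste0("w", 1:30)
  withr::with_seed(77, {
    for (rep in 1:25) {
      train <- random_corpora(sample(2:8, 1), 30, alphabet)
      test <- random_corpora(3, 30, alphabet, allow_empty = TRUE)
      mf <- if (rep %% 3 == 0) sample(3:10, 1) else NULL
      model <- fit_tfidf(train, max_features = mf)
      oracle <- brute_tfidf_fit(train, max_features = mf)
      expect_identical(model$vocabulary, oracle$vocab)
      got <- apply_tfidf(model, test)
      for (i in seq_along(test)) {
        expect_equal(unname(got[i, ]),
                     brute_tfidf_encode(oracle, test[[i]]),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("load_embedding parses word2vec text with and without header", {
  f <- withr::local_tempfile(lines = c("rib 1 0", "fracture 0 1"))
  e <- load_embedding(f)
  expect_equal(e$dimension, 2L)
  expect_equal(nrow(e$vectors), 2L)

  fh <- withr::local_tempfile(lines = c("2 3", "rib 1 0 2", "bruise 0 1 3"))
  eh <- load_embedding(fh)
  expect_equal(eh$dimension, 3L)

  bad <- withr::local_tempfile(lines = c("rib 1 0 2", "bruise 0 1"))
  expect_error(load_embedding(bad), "dimension")
  empty <- withr::local_tempfile(lines = character())
  expect_error(load_embedding(empty), "empty")

  dupf <- withr::local_tempfile(lines = c("rib 1 0", "rib 9 9", "ulna 0 1"))
  expect_warning(dup <- load_embedding(dupf), "duplicate")
  expect_equal(nrow(dup$vectors), 2L)
  expect_equal(unname(dup$vectors["rib", ]), c(1, 0))
})

test_that("encode_embedding pools vectors and handles OOV deterministically", {
  f <- withr::local_tempfile(lines = c("rib 1 0", "fracture 0 1"))
  e <- load_embedding(f, oov_seed = 5)
  out <- encode_embedding(e, list(c("rib", "fracture")))
  expect_equal(out$features[1, ], c(0.5, 0.5))
  expect_equal(unname(out$coverage), 1.0)

  rep2 <- encode_embedding(e, list(c("rib", "rib")))
  expect_equal(rep2$features[1, ], c(1, 0))

  a <- encode_embedding(e, list("unseenword"))
  b <- encode_embedding(e, list("unseenword"))
  expect_equal(unname(a$coverage), 0)
  expect_identical(a$features, b$features)
  expect_true(all(abs(a$features) <= 0.5 / e$dimension))

  expect_warning(z <- encode_embedding(e, list(character())), "empty")
  expect_equal(z$features[1, ], c(0, 0))
  expect_equal(unname(z$coverage), 0)

  s <- encode_embedding(e, list(c("rib", "fracture")), pooling = "sum")
  expect_equal(s$features[1, ], c(1, 1))
})

test_that("embedding coverage equals the in-table token fraction on synthetic text", {
  lex <- generate_lexicon(2, 0, seed = 12)
  cfg <- cohort_config(10, lex, p_present_pos = 1 - 1e-9,
                       p_present_neg = 1 - 1e-9, seed = 31,
                       corpus_words = c(meanlog = log(150), sdlog = 0.3))
  corpora <- run_preprocess(cfg)$corpora
  phrase_tokens <- unique(unlist(strsplit(lex$phrase, " ")))
  lines <- paste(phrase_tokens, "1", "0")
  f <- withr::local_tempfile(lines = lines)
  e <- load_embedding(f)
  out <- encode_embedding(e, corpora)
  frac <- vapply(corpora$tokens, function(tk) mean(tk %in% phrase_tokens),
                 numeric(1))
  expect_equal(unname(out$coverage), unname(frac))
  expect_true(all(out$coverage < 0.5))  # background dominates
})

test_that("encode_rules applies the 1/0/-1 scheme on contiguous runs", {
  lex <- rule_lexicon(
    c("rib fracture", "consistent mechanism", "retinal hemorrhage"),
    c("positive", "negative", "positive"))
  corpus <- c("infant", "rib", "fracture", "noted", "story",
              "consistent", "mechanism", "described")
  v <- encode_rules(lex, list(corpus))[1, ]
  expect_equal(unname(v), c(1L, 0L, -1L))

  expect_equal(unname(encode_rules(lex, list(character()))[1, ]),
               c(-1L, -1L, -1L))

  # contiguity: reversed word order is not a match
  expect_equal(unname(encode_rules(lex, list(c("fracture", "rib")))[1, ]),
               c(-1L, -1L, -1L))
})

test_that("rules output alphabet and -1 count follow the presence pattern", {
  lex <- generate_lexicon(5, 3, seed = 13)
  cfg <- cohort_config(20, lex, seed = 17,
                       corpus_words = c(meanlog = log(250), sdlog = 0.4))
  cohort <- generate_cohort(cfg)
  corpora <- cohort$notes |> truncate_at_cap() |> build_corpus()
  rb <- encode_rules(lex, corpora)
  expect_true(all(rb %in% c(-1L, 0L, 1L)))
  truth_wide <- cohort$truth |>
    tidyr::pivot_wider(names_from = phrase, values_from = present)
  truth_m <- as.matrix(truth_wide[match(corpora$patient_id,
                                        truth_wide$patient_id),
                                  lex$phrase])
  expect_equal(unname(rowSums(rb == -1L)), unname(rowSums(truth_m == 0)))
})

test_that("lexicon TSV round-trips with polarity codes", {
  lex <- generate_lexicon(3, 2, seed = 14)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, f)
  back <- read_lexicon_tsv(f)
  expect_equal(back$phrase, lex$phrase)
  expect_equal(back$polarity, lex$polarity)

  # phrases are cleaned on read: punctuation and stop words drop out
  raw <- withr::local_tempfile(
    lines = c("History of domestic violence.\tpos", "witnessed fall\tneg"))
  parsed <- read_lexicon_tsv(raw)
  expect_equal(parsed$phrase[1], "history domestic violence")
})

test_that("starter lexicon fixture loads and is polarized", {
  lex <- starter_lexicon()
  expect_s3_class(lex, "rule_lexicon")
  expect_true(all(c("positive", "negative") %in% lex$polarity))
  expect_true("history domestic violence" %in% lex$phrase)
})
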