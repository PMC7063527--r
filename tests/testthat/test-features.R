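# Feature extraction: pronoun categories, subfeature counts, sentiment,
# assembly and task selection.

test_that("personal nouns are counted per category, one category per token", {
  reg <- test_registry()
  expect_equal(count_personal_nouns(c("i", "love", "my", "son"), reg),
               c(personal_first = 2L, personal_second = 0L,
                 personal_third = 0L, personal_other = 1L))
  expect_equal(count_personal_nouns("ur", reg)[["personal_second"]], 1L)
  expect_equal(sum(count_personal_nouns(character(0), reg)), 0L)
  # apostrophe entries match contractions by prefix
  counts <- count_personal_nouns(c("i'm", "he's", "they'll"), reg)
  expect_equal(counts[["personal_first"]], 1L)
  expect_equal(counts[["personal_third"]], 2L)
})

test_that("subfeature counts follow the match oracle on the worked tweets", {
  reg <- test_registry()
  overdose <- reg$subfeatures[["nonmedical.overdose"]]
  route <- reg$subfeatures[["nonmedical.route"]]
  stems1 <- to_content_stems(
    tokenize("Time to pop the Ritalin I been keeping")$raw_tokens)
  expect_equal(count_subfeature(stems1, overdose), 1L)
  stems2 <- to_content_stems(tokenize(
    "When I was young I snorted my Concerta only for the head rush"
  )$raw_tokens)
  expect_equal(count_subfeature(stems2, route), 1L)
  expect_equal(count_subfeature(stems1, route), 0L)
  # repeated tokens count repeatedly
  expect_equal(count_subfeature(c("snort", "snort"), route), 2L)
})

test_that("sentiment score is the signed count of opinion words", {
  lex <- test_sentiment()
  expect_equal(sentiment_score("wtf", lex), -1L)
  expect_equal(sentiment_score(c("good", "good", "bad"), lex), 1L)
  expect_equal(sentiment_score(character(0), lex), 0L)
  set.seed(21)
  toks <- sample(c(lex$positive[1:5], lex$negative[1:5], "zzzz"), 40,
                 replace = TRUE)
  expect_lte(abs(sentiment_score(toks, lex)), length(toks))
})

test_that("feature vectors assemble all 23 fields deterministically", {
  reg <- test_registry()
  lex <- test_sentiment()
  tt <- tokenize("Time to pop the Ritalin I been keeping")
  v <- extract_features(tt, reg, lex)
  expect_length(v, 23L)
  expect_equal(v[["nm_overdose"]], 1)
  expect_equal(v[["personal_first"]], 1)
  expect_equal(v[["url"]], 0)
  expect_identical(v, extract_features(tt, reg, lex))

  blank <- extract_features(tokenize("zzzq xxkw"), reg, lex)
  expect_true(all(blank == 0))

  # a non-lexicon token never changes any count field
  v2 <- extract_features(
    tokenize("Time to pop the Ritalin I been keeping zzzq"), reg, lex)
  expect_identical(v2, v)

  # count fields bounded by the number of content stems
  stems <- to_content_stems(tt$raw_tokens)
  term_fields <- setdiff(names(v), c("personal_first", "personal_second",
                                     "personal_third", "personal_other",
                                     "sentiment", "url"))
  expect_true(all(v[term_fields] <= length(stems)))
})

test_that("task selection yields the documented 14- and 15-dim layouts", {
  reg <- test_registry()
  lex <- test_sentiment()
  expect_length(feature_order("nonmedical", reg), 14L)
  expect_length(feature_order("side_effects", reg), 15L)
  expect_false(any(grepl("^se_", feature_order("nonmedical", reg))))
  expect_false(any(grepl("^nm_|^medical$",
                         feature_order("side_effects", reg))))

  v <- extract_features(tokenize("zzzq xxkw"), reg, lex)
  expect_equal(unname(select_task_features(v, "nonmedical", reg)),
               rep(0, 14))
  expect_equal(unname(select_task_features(v, "side_effects", reg)),
               rep(0, 15))
  expect_error(select_task_features(v, "other"))

  feats <- test_features(n = 60L, seed = 3L)
  X <- select_task_features(feats, "nonmedical", reg)
  expect_equal(dim(X), c(60L, 14L))
  expect_identical(colnames(X), feature_order("nonmedical", reg))
})
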