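# Synthetic corpus generator: determinism, prevalence bounds, feature-label
# coupling, manifest recounts.

test_that("same configuration and seed reproduce the corpus byte for byte", {
  cfg <- synthetic_config(n_tweets = 150L, seed = 23L)
  a <- generate_corpus(cfg, test_registry(), test_sentiment())
  b <- generate_corpus(cfg, test_registry(), test_sentiment())
  expect_identical(a$tweets, b$tweets)
  expect_identical(a$manifest$injected_terms, b$manifest$injected_terms)
})

test_that("realized prevalences stay within 3 binomial sd of the target", {
  corpus <- generate_corpus(synthetic_config(n_tweets = 10000L, seed = 2L),
                            test_registry(), test_sentiment())
  stats <- corpus_manifest(corpus)
  # 3 sd at p = 0.052, n = 10000: 0.052 +/- 0.0067
  expect_gte(stats$prevalence_nonmedical, 0.045)
  expect_lte(stats$prevalence_nonmedical, 0.059)
  expect_gte(stats$prevalence_side_effects, 0.048)
  expect_lte(stats$prevalence_side_effects, 0.062)
  # monthly uniformity over the 12 collection months
  month <- format(corpus$tweets$created_at, "%Y-%m", tz = "UTC")
  shares <- table(month) / length(month)
  expect_length(shares, 12L)
  expect_true(all(shares >= 0.05 & shares <= 0.12))
})

test_that("every positive carries an injected term its features detect", {
  corpus <- test_corpus(n = 400L, seed = 7L)
  inj <- corpus$manifest$injected_terms
  tw <- corpus$tweets
  expect_true(all(lengths(inj[tw$gold_nonmedical == 1L |
                                tw$gold_side_effects == 1L]) >= 1L))
  expect_true(all(startsWith(unlist(inj[tw$gold_nonmedical == 1L &
                                          tw$gold_side_effects == 0L]),
                             "nonmedical:")))
  feats <- test_features(n = 400L, seed = 7L)
  nm_cols <- grep("^nm_", names(feats), value = TRUE)
  se_cols <- grep("^se_", names(feats), value = TRUE)
  expect_true(all(rowSums(feats[feats$gold_nonmedical == 1L, nm_cols]) >= 1))
  expect_true(all(rowSums(feats[feats$gold_side_effects == 1L, se_cols]) >= 1))
})

test_that("degenerate and forced configurations behave as specified", {
  expect_error(synthetic_config(p_both = 0.1, prevalence_nonmedical = 0.05),
               "infeasible")
  all_neg <- generate_corpus(
    synthetic_config(n_tweets = 80L, prevalence_nonmedical = 0,
                     prevalence_side_effects = 0, p_both = 0, seed = 3L),
    test_registry(), test_sentiment())
  expect_equal(sum(all_neg$tweets$gold_nonmedical), 0L)
  feats <- featurize_corpus(all_neg$tweets, test_registry(),
                            test_sentiment())
  expect_error(train_and_evaluate(feats, "nonmedical", point_config()),
               "both classes")

  forced_url <- generate_corpus(
    synthetic_config(n_tweets = 120L, p_url_neg = 1, seed = 4L),
    test_registry(), test_sentiment())
  expect_equal(corpus_manifest(forced_url)$url_rate_negative, 1)

  empty <- generate_corpus(synthetic_config(n_tweets = 0L, seed = 1L),
                           test_registry(), test_sentiment())
  expect_equal(corpus_manifest(empty)$n, 0L)
})

test_that("contamination knob plants lexicon collisions only when asked", {
  reg <- test_registry()
  clean_feats <- test_features(n = 400L, seed = 7L)
  fully_neg <- clean_feats$gold_nonmedical == 0L &
    clean_feats$gold_side_effects == 0L
  nm_cols <- grep("^nm_", names(clean_feats), value = TRUE)
  expect_equal(sum(rowSums(clean_feats[fully_neg, nm_cols])), 0)

  dirty <- generate_corpus(
    synthetic_config(n_tweets = 400L, seed = 7L, p_confounder_neg = 0.5),
    reg, test_sentiment())
  dirty_feats <- featurize_corpus(dirty$tweets, reg, test_sentiment())
  dn <- dirty_feats$gold_nonmedical == 0L &
    dirty_feats$gold_side_effects == 0L
  term_cols <- grep("^nm_|^se_", names(dirty_feats), value = TRUE)
  expect_gt(sum(rowSums(dirty_feats[dn, term_cols]) > 0), 0)
})

test_that("manifest statistics equal a brute-force recount", {
  corpus <- test_corpus(n = 500L, seed = 29L)
  stats <- corpus_manifest(corpus)
  tw <- corpus$tweets
  expect_equal(stats$n_nonmedical, sum(tw$gold_nonmedical))
  expect_equal(stats$n_side_effects, sum(tw$gold_side_effects))
  expect_equal(stats$n_both,
               sum(tw$gold_nonmedical == 1L & tw$gold_side_effects == 1L))
  pos <- tw$gold_nonmedical == 1L | tw$gold_side_effects == 1L
  expect_equal(stats$url_rate_negative,
               mean(detect_url(tw$text[!pos])))
  expect_equal(stats$mean_injected_per_positive,
               mean(lengths(corpus$manifest$injected_terms[pos])))
})
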