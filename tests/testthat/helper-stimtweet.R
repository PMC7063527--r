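# shared fixtures, built in code and cached for the test session

the <- new.env(parent = emptyenv())

test_registry <- function() {
  if (is.null(the$registry)) the$registry <- load_default_lexicons()
  the$registry
}

test_sentiment <- function() {
  if (is.null(the$sentiment)) the$sentiment <- load_sentiment_lexicon()
  the$sentiment
}

# small deterministic labeled corpus for model/evaluate tests
test_corpus <- function(n = 400L, seed = 7L, ...) {
  generate_corpus(synthetic_config(n_tweets = n, seed = seed, ...),
                  test_registry(), test_sentiment())
}

test_features <- function(n = 400L, seed = 7L, ...) {
  key <- paste0("feats_", n, "_", seed)
  if (is.null(the[[key]])) {
    the[[key]] <- featurize_corpus(test_corpus(n, seed, ...)$tweets,
                                   test_registry(), test_sentiment())
  }
  the[[key]]
}

# coarse power-of-two grid: the study-size configuration used throughout
# the suite (full default grid is exercised implicitly via svm_config())
coarse_config <- function(seed = 1L, cv_folds = 10L) {
  svm_config(cost_grid = 2^seq(-2, 10, 2), gamma_grid = 2^seq(-9, 1, 2),
             cv_folds = cv_folds, seed = seed)
}

# tiny single-point grid for plumbing tests where tuning is irrelevant
point_config <- function(seed = 1L, cv_folds = 5L) {
  svm_config(cost_grid = 4, gamma_grid = 0.125, cv_folds = cv_folds,
             seed = seed)
}

# a tiny hand-made corpus data frame
mini_corpus <- function(texts, t0 = "2019-01-15 12:00:00") {
  n <- length(texts)
  data.frame(
    tweet_id = sprintf("m%03d", seq_len(n)),
    created_at = as.POSIXct(t0, tz = "UTC") + seq_len(n) * 3600,
    text = texts,
    stringsAsFactors = FALSE
  )
}
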