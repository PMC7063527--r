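# Synthetic labeled tweet corpora with the statistical structure the
# analysis assumes: ~5% positive prevalence per task, positives enriched in
# lexicon terms and first-person nouns, negatives carrying news/lyrics-like
# noise and URLs. Text is template-assembled token soup; every downstream
# operation is token/stem based, so no natural-language realism is needed.

#' Search terms for methylphenidate and its brand names
#'
#' The 14 drug-name search terms used to assemble a methylphenidate corpus.
#'
#' @return character vector of 14 terms.
#' @export
default_search_terms <- function() {
  c("methylphenidate", "Aptensio", "Biphentin", "Concerta", "Daytrana",
    "Equasym", "Jornay", "Medikinet", "Metadate", "Methylin", "Quillichew",
    "Quillivant", "Ritalin", "Rubifen")
}

#' Synthetic corpus configuration
#'
#' Defaults reproduce the study conditions the pipeline assumes: positive
#' prevalence about 5.2% (nonmedical use) and 5.5% (side effects), with 0.3%
#' of tweets positive for both; positives carry 1-3 injected lexicon terms
#' and are mostly first-person; negatives are news/lyrics-like noise with
#' frequent URLs. An optional contamination rate (`p_confounder_neg`) plants
#' everyday lexicon-colliding words in negatives to stress precision; it is
#' off by default.
#'
#' @param n_tweets corpus size.
#' @param prevalence_nonmedical,prevalence_side_effects positive rates per
#'   task.
#' @param p_both probability of a tweet positive for both tasks (must not
#'   exceed either prevalence).
#' @param signal_terms_range integer range (min, max) of injected lexicon
#'   terms per positive tweet.
#' @param p_first_person_pos,p_first_person_neg probability of first-person
#'   tokens in positives / negatives.
#' @param p_url_pos,p_url_neg probability of a URL in positives / negatives.
#' @param p_negative_sentiment_word_se probability that a side-effect
#'   positive carries a negative opinion-lexicon word.
#' @param p_confounder_neg probability that a negative tweet contains one
#'   everyday word that is also a lexicon stem ("need", "work", "test").
#'   Default 0: the default corpus structure keeps negatives free of
#'   lexicon collisions; raise this to stress classifier precision.
#' @param p_medical_neg,p_medical_pos probability of a medical-use term in
#'   negatives / positives (patients tweeting about treatment are
#'   negatives for nonmedical use).
#' @param noise_vocab_size number of distinct pseudo-word noise tokens.
#' @param tokens_per_tweet integer range (min, max) of tokens per tweet.
#' @param seed RNG seed; the corpus is a deterministic function of the
#'   configuration.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tweets = 2000L,
                             prevalence_nonmedical = 0.052,
                             prevalence_side_effects = 0.055,
                             p_both = 0.003,
                             signal_terms_range = c(1L, 3L),
                             p_first_person_pos = 0.9,
                             p_first_person_neg = 0.3,
                             p_url_pos = 0.05,
                             p_url_neg = 0.4,
                             p_negative_sentiment_word_se = 0.5,
                             p_confounder_neg = 0,
                             p_medical_neg = 0.25,
                             p_medical_pos = 0.05,
                             noise_vocab_size = 500L,
                             tokens_per_tweet = c(8L, 20L),
                             seed = 1L) {
  probs <- c(prevalence_nonmedical, prevalence_side_effects, p_both,
             p_first_person_pos, p_first_person_neg, p_url_pos, p_url_neg,
             p_negative_sentiment_word_se, p_confounder_neg,
             p_medical_neg, p_medical_pos)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_both > prevalence_nonmedical || p_both > prevalence_side_effects) {
    stop("infeasible config: p_both exceeds a task prevalence")
  }
  if (prevalence_nonmedical + prevalence_side_effects - p_both > 1) {
    stop("infeasible config: label probabilities exceed 1")
  }
  stopifnot(n_tweets >= 0, length(signal_terms_range) == 2L,
            signal_terms_range[1] >= 1L,
            signal_terms_range[2] >= signal_terms_range[1],
            length(tokens_per_tweet) == 2L, tokens_per_tweet[1] >= 4L,
            tokens_per_tweet[2] >= tokens_per_tweet[1],
            noise_vocab_size >= 10L)
  structure(
    list(n_tweets = as.integer(n_tweets),
         prevalence_nonmedical = prevalence_nonmedical,
         prevalence_side_effects = prevalence_side_effects,
         p_both = p_both,
         signal_terms_range = as.integer(signal_terms_range),
         p_first_person_pos = p_first_person_pos,
         p_first_person_neg = p_first_person_neg,
         p_url_pos = p_url_pos, p_url_neg = p_url_neg,
         p_negative_sentiment_word_se = p_negative_sentiment_word_se,
         p_confounder_neg = p_confounder_neg,
         p_medical_neg = p_medical_neg, p_medical_pos = p_medical_pos,
         noise_vocab_size = as.integer(noise_vocab_size),
         tokens_per_tweet = as.integer(tokens_per_tweet),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# surface word for a stem: a token whose content stem equals the stem.
# Tries inflected candidates first; returns NA when no candidate stems back
# (a few lexicon entries, e.g. "lbs", have no such surface form).
surface_for_stem <- function(stem, stopwords = default_stopwords()) {
  yform <- if (endsWith(stem, "i")) sub("i$", "y", stem) else NULL
  candidates <- unique(c(yform, paste0(stem, "ed"), paste0(stem, "ing"),
                         stem, paste0(stem, "e"), paste0(stem, "s")))
  for (cand in candidates) {
    out <- to_content_stems(cand, stopwords)
    if (length(out) == 1L && out == stem) return(cand)
  }
  NA_character_
}

# per-group injectable surface forms: list(group -> named chr vector
# surface forms, names = stems)
build_injection_table <- function(registry,
                                  stopwords = default_stopwords()) {
  groups <- list()
  for (sub in registry$subfeatures) {
    if (sub$group == "personal_noun") next
    for (stem in sub$stems) {
      if (endsWith(stem, "'")) next
      surf <- surface_for_stem(stem, stopwords)
      if (!is.na(surf)) {
        groups[[sub$group]] <- c(groups[[sub$group]],
                                 stats::setNames(surf, stem))
      }
    }
  }
  groups
}

# deterministic pseudo-word noise vocabulary that cannot collide with any
# lexicon stem, sentiment word, stop word or drug name
build_noise_vocab <- function(n, registry, sentiment,
                              stopwords = default_stopwords()) {
  reserved <- c(
    unlist(lapply(registry$subfeatures, `[[`, "stems"), use.names = FALSE),
    sentiment$positive, sentiment$negative, stopwords,
    tolower(default_search_terms())
  )
  consonants <- strsplit("bcdfgjklmnprstvz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  vocab <- character(0)
  while (length(vocab) < n) {
    need <- n - length(vocab)
    words <- vapply(seq_len(need), function(i) {
      syl <- sample(2:3, 1)
      paste0(vapply(seq_len(syl), function(j)
        paste0(sample(consonants, 1), sample(vowels, 1),
               sample(consonants, 1)), character(1)), collapse = "")
    }, character(1))
    stems <- porter_stem(words)
    ok <- !(words %in% reserved) & !(stems %in% reserved)
    vocab <- unique(c(vocab, words[ok]))
  }
  vocab[seq_len(n)]
}

#' Generate a synthetic labeled tweet corpus
#'
#' Assembles tweets from templates: one drug mention sampled from
#' [default_search_terms()], pronoun tokens, injected lexicon terms matching
#' the gold label, a negative sentiment word for side-effect positives,
#' pseudo-word noise, and an optional URL. Timestamps are uniform over
#' August 2018 - July 2019 (UTC). The corpus is deterministic given the
#' configuration (including its seed).
#'
#' @param config a [synthetic_config()].
#' @param registry a `lexicon_registry`.
#' @param sentiment a `sentiment_lexicon`.
#' @return object of class `synthetic_corpus`: list with `tweets` (a corpus
#'   data frame with gold labels) and `manifest` (configuration, seed, and
#'   the per-tweet injected-term log).
#' @examples
#' corpus <- generate_corpus(synthetic_config(n_tweets = 50, seed = 7))
#' head(corpus$tweets$text, 3)
#' @export
generate_corpus <- function(config = synthetic_config(),
                            registry = load_default_lexicons(),
                            sentiment = load_sentiment_lexicon()) {
  stopifnot(inherits(config, "synthetic_config"))
  stopwords <- default_stopwords()
  inject <- build_injection_table(registry, stopwords)
  set.seed(config$seed)
  noise <- build_noise_vocab(config$noise_vocab_size, registry, sentiment,
                             stopwords)
  n <- config$n_tweets
  # joint label assignment
  p_both <- config$p_both
  p_nm_only <- config$prevalence_nonmedical - p_both
  p_se_only <- config$prevalence_side_effects - p_both
  p_neg <- 1 - p_nm_only - p_se_only - p_both
  kind <- if (n > 0L) {
    sample(c("negative", "nm", "se", "both"), n, replace = TRUE,
           prob = c(p_neg, p_nm_only, p_se_only, p_both))
  } else character(0)
  gold_nm <- as.integer(kind %in% c("nm", "both"))
  gold_se <- as.integer(kind %in% c("se", "both"))

  t0 <- as.POSIXct("2018-08-01 00:00:00", tz = "UTC")
  t1 <- as.POSIXct("2019-08-01 00:00:00", tz = "UTC")
  created <- t0 + stats::runif(n, 0, as.numeric(difftime(t1, t0,
                                                         units = "secs")))
  created <- round(created)

  first_person <- c("i", "my", "me", "i'm")
  third_person <- c("he", "she", "they", "his", "her")
  news_words <- c("article", "link", "video", "song", "lyric", "album",
                  "report", "review", "press", "update")
  confounders <- intersect(c("need", "want", "work", "test", "final",
                             "focus", "paper", "shot", "pot"),
                           unlist(lapply(inject, names), use.names = FALSE))
  neg_sent <- sentiment$negative
  terms <- default_search_terms()

  texts <- character(n)
  url_flag <- integer(n)
  injected_log <- vector("list", n)
  for (i in seq_len(n)) {
    positive <- kind[i] != "negative"
    tokens <- sample(terms, 1L)  # drug mention
    log_i <- character(0)
    # pronouns
    p_fp <- if (positive) config$p_first_person_pos else
      config$p_first_person_neg
    if (stats::runif(1) < p_fp) {
      tokens <- c(tokens, sample(first_person, sample(1:2, 1L)))
    } else if (stats::runif(1) < 0.5) {
      tokens <- c(tokens, sample(third_person, 1L))
    }
    # injected lexicon signal
    inject_from <- function(group) {
      k <- sample(seq(config$signal_terms_range[1],
                      config$signal_terms_range[2]), 1L)
      pool <- inject[[group]]
      picks <- sample(seq_along(pool), k, replace = TRUE)
      log_i <<- c(log_i, paste0(group, ":", names(pool)[picks]))
      unname(pool[picks])
    }
    if (kind[i] %in% c("nm", "both")) {
      tokens <- c(tokens, inject_from("nonmedical"))
    }
    if (kind[i] %in% c("se", "both")) {
      tokens <- c(tokens, inject_from("side_effect"))
      if (stats::runif(1) < config$p_negative_sentiment_word_se) {
        tokens <- c(tokens, sample(neg_sent, 1L))
      }
    }
    # medical-use mentions (mostly genuine patients, i.e. negatives)
    p_med <- if (positive) config$p_medical_pos else config$p_medical_neg
    if (stats::runif(1) < p_med) {
      tokens <- c(tokens, unname(inject$medical[sample(
        length(inject$medical), 1L)]))
    }
    if (!positive) {
      if (stats::runif(1) < config$p_confounder_neg &&
          length(confounders) > 0L) {
        stem <- sample(confounders, 1L)
        grp <- if (stem %in% names(inject$nonmedical)) "nonmedical" else
          "side_effect"
        tokens <- c(tokens, unname(inject[[grp]][stem]))
      }
      tokens <- c(tokens, sample(news_words, sample(1:3, 1L)))
    }
    # pad with noise to the target length
    target <- sample(seq(config$tokens_per_tweet[1],
                         config$tokens_per_tweet[2]), 1L)
    if (length(tokens) < target) {
      tokens <- c(tokens, sample(noise, target - length(tokens),
                                 replace = TRUE))
    }
    tokens <- sample(tokens)  # shuffle word order
    p_url <- if (positive) config$p_url_pos else config$p_url_neg
    if (stats::runif(1) < p_url) {
      tokens <- c(tokens, paste0("https://t.co/",
                                 paste0(sample(letters, 6L, replace = TRUE),
                                        collapse = "")))
      url_flag[i] <- 1L
    }
    texts[i] <- paste(tokens, collapse = " ")
    injected_log[[i]] <- log_i
  }

  tweets <- data.frame(
    tweet_id = sprintf("t%06d", seq_len(max(n, 0L))),
    created_at = created, text = texts,
    gold_nonmedical = gold_nm, gold_side_effects = gold_se,
    stringsAsFactors = FALSE
  )
  if (n == 0L) tweets <- tweets[0, ]
  structure(
    list(tweets = tweets,
         manifest = list(config = unclass(config), seed = config$seed,
                         injected_terms = injected_log,
                         lexicon_version = registry$version)),
    class = "synthetic_corpus"
  )
}

#' Summary statistics of a synthetic corpus
#'
#' Recounts realized prevalences, URL rates by class, and mean injected
#' terms per positive tweet, directly from the generated records.
#'
#' @param corpus a `synthetic_corpus`.
#' @return object of class `corpus_manifest_stats`: list with `n`,
#'   `n_nonmedical`, `n_side_effects`, `n_both`, `prevalence_nonmedical`,
#'   `prevalence_side_effects`, `url_rate_positive`, `url_rate_negative`,
#'   `mean_injected_per_positive`.
#' @export
corpus_manifest <- function(corpus) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  tw <- corpus$tweets
  n <- nrow(tw)
  if (n == 0L) {
    return(structure(list(
      n = 0L, n_nonmedical = 0L, n_side_effects = 0L, n_both = 0L,
      prevalence_nonmedical = 0, prevalence_side_effects = 0,
      url_rate_positive = 0, url_rate_negative = 0,
      mean_injected_per_positive = 0), class = "corpus_manifest_stats"))
  }
  has_url <- detect_url(tw$text)
  pos <- tw$gold_nonmedical == 1L | tw$gold_side_effects == 1L
  n_inj <- lengths(corpus$manifest$injected_terms)
  structure(list(
    n = n,
    n_nonmedical = sum(tw$gold_nonmedical),
    n_side_effects = sum(tw$gold_side_effects),
    n_both = sum(tw$gold_nonmedical == 1L & tw$gold_side_effects == 1L),
    prevalence_nonmedical = mean(tw$gold_nonmedical),
    prevalence_side_effects = mean(tw$gold_side_effects),
    url_rate_positive = if (any(pos)) mean(has_url[pos]) else 0,
    url_rate_negative = if (any(!pos)) mean(has_url[!pos]) else 0,
    mean_injected_per_positive = if (any(pos)) mean(n_inj[pos]) else 0
  ), class = "corpus_manifest_stats")
}

#' @export
print.corpus_manifest_stats <- function(x, ...) {
  cat("Synthetic corpus:", x$n, "tweets\n")
  cat(sprintf("  nonmedical use: %d (%.2f%%)\n", x$n_nonmedical,
              100 * x$prevalence_nonmedical))
  cat(sprintf("  side effects:   %d (%.2f%%)\n", x$n_side_effects,
              100 * x$prevalence_side_effects))
  cat(sprintf("  both:           %d\n", x$n_both))
  cat(sprintf("  URL rate: %.2f (positives) / %.2f (negatives)\n",
              x$url_rate_positive, x$url_rate_negative))
  cat(sprintf("  mean injected terms per positive: %.2f\n",
              x$mean_injected_per_positive))
  invisible(x)
}
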