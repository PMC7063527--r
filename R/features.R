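# Feature extraction: per-tweet numeric vector of lexicon-match counts,
# sentiment score, and URL flag.

# canonical short feature names per (group, subfeature_id)
feature_name <- function(group, sub_id) {
  switch(group,
    personal_noun = paste0("personal_", switch(sub_id, others = "other",
      sub("_person$", "", sub_id))),
    nonmedical = paste0("nm_", sub_id),
    medical = "medical",
    side_effect = paste0("se_", switch(sub_id,
      psychiatric = "psych", gastrointestinal = "gi",
      neurological = "neuro", sweating = "sweat", sub_id)),
    stop("unknown group: ", group)
  )
}

# does `token` match `stem` under the subfeature's match mode?
# stems ending in an apostrophe are truncated contraction forms and always
# match by prefix ("i'" matches "i'm", "i'll", ...)
match_stems <- function(tokens, stems, match_mode = "exact_stem") {
  if (length(tokens) == 0L) return(logical(0))
  prefix_stems <- stems[endsWith(stems, "'") | match_mode == "raw_prefix"]
  exact_stems <- setdiff(stems, prefix_stems)
  hit <- tokens %in% exact_stems
  for (p in prefix_stems) {
    hit <- hit | startsWith(tokens, p)
  }
  hit
}

#' Count personal-noun tokens by category
#'
#' Matches raw tokens (before stop-word removal, since pronouns are stop
#' words) against the four personal-noun categories: first person, second
#' person, third person, and other persons (family/friends). A token counts
#' in at most one category; categories are checked in registry order and the
#' first match wins.
#'
#' @param raw_tokens character vector from [tokenize()].
#' @param registry a `lexicon_registry`.
#' @return named integer vector
#'   `c(personal_first, personal_second, personal_third, personal_other)`.
#' @examples
#' reg <- load_default_lexicons()
#' count_personal_nouns(c("i", "love", "my", "son"), reg)
#' @export
count_personal_nouns <- function(raw_tokens, registry) {
  stopifnot(inherits(registry, "lexicon_registry"))
  subs <- Filter(function(s) s$group == "personal_noun",
                 registry$subfeatures)
  counts <- integer(length(subs))
  names(counts) <- vapply(subs, function(s)
    feature_name(s$group, s$subfeature_id), character(1))
  if (length(raw_tokens) > 0L) {
    unclaimed <- rep(TRUE, length(raw_tokens))
    for (k in seq_along(subs)) {
      hit <- match_stems(raw_tokens, subs[[k]]$stems,
                         subs[[k]]$match_mode) & unclaimed
      counts[k] <- sum(hit)
      unclaimed <- unclaimed & !hit
    }
  }
  counts
}

#' Count lexicon-subfeature matches in content stems
#'
#' Number of stem tokens matching any stem of the subfeature; repeated
#' tokens count repeatedly.
#'
#' @param content_stems character vector from [to_content_stems()].
#' @param subfeature a `subfeature_lexicon` entry of a registry.
#' @return integer count.
#' @examples
#' reg <- load_default_lexicons()
#' stems <- to_content_stems(tokenize("Time to pop the Ritalin")$raw_tokens)
#' count_subfeature(stems, reg$subfeatures[["nonmedical.overdose"]])
#' @export
count_subfeature <- function(content_stems, subfeature) {
  stopifnot(inherits(subfeature, "subfeature_lexicon"))
  if (length(content_stems) == 0L) return(0L)
  sum(match_stems(content_stems, subfeature$stems, subfeature$match_mode))
}

#' Opinion-lexicon sentiment score
#'
#' Signed integer sentiment: each raw token in the positive list counts +1,
#' each in the negative list -1. Matching is exact on raw lowercase tokens
#' (unstemmed).
#'
#' @param raw_tokens character vector from [tokenize()].
#' @param sentiment a `sentiment_lexicon`.
#' @return integer score; its magnitude is at most `length(raw_tokens)`.
#' @examples
#' sentiment_score(c("wtf"), load_sentiment_lexicon())
#' @export
sentiment_score <- function(raw_tokens, sentiment) {
  stopifnot(inherits(sentiment, "sentiment_lexicon"))
  if (length(raw_tokens) == 0L) return(0L)
  sum(raw_tokens %in% sentiment$positive) -
    sum(raw_tokens %in% sentiment$negative)
}

#' Full feature vector for one tokenized tweet
#'
#' Assembles the 23 supervised-learning features: 4 personal-noun counts,
#' 7 nonmedical-use counts, 1 medical-use count, 9 side-effect counts, the
#' sentiment score, and the URL flag. Deterministic in its inputs.
#'
#' @param tokenized a `tokenized_tweet` carrying `raw_tokens`, `has_url`
#'   and (from [tokenize_corpus()]) `content_stems`; if `content_stems` is
#'   absent it is computed with [to_content_stems()].
#' @param registry a `lexicon_registry`.
#' @param sentiment a `sentiment_lexicon`.
#' @param stopwords stop-word list used only if stems must be computed.
#' @return named numeric vector of length 23, in registry order followed by
#'   `sentiment` and `url`.
#' @export
extract_features <- function(tokenized, registry, sentiment,
                             stopwords = default_stopwords()) {
  stopifnot(inherits(tokenized, "tokenized_tweet"),
            inherits(registry, "lexicon_registry"),
            inherits(sentiment, "sentiment_lexicon"))
  stems <- tokenized$content_stems
  if (is.null(stems)) {
    stems <- to_content_stems(tokenized$raw_tokens, stopwords)
  }
  v <- count_personal_nouns(tokenized$raw_tokens, registry)
  term_subs <- Filter(function(s) s$group != "personal_noun",
                      registry$subfeatures)
  for (sub in term_subs) {
    v[[feature_name(sub$group, sub$subfeature_id)]] <-
      count_subfeature(stems, sub)
  }
  v[["sentiment"]] <- sentiment_score(tokenized$raw_tokens, sentiment)
  v[["url"]] <- as.integer(tokenized$has_url)
  v
}

#' Documented feature ordering per classification task
#'
#' The nonmedical-use classifier uses personal nouns, the 7 nonmedical
#' subfeatures, medical-use terms, sentiment and URL (14 features); the
#' side-effects classifier uses personal nouns, the 9 side-effect
#' subfeatures, sentiment and URL (15 features). Each classifier excludes
#' the other task's term group.
#'
#' @param task `"nonmedical"` or `"side_effects"`.
#' @param registry a `lexicon_registry` (defines subfeature order).
#' @return character vector of feature names in model column order.
#' @export
feature_order <- function(task, registry = load_default_lexicons()) {
  task <- match.arg(task, c("nonmedical", "side_effects"))
  nm <- function(g) {
    subs <- Filter(function(s) s$group == g, registry$subfeatures)
    vapply(subs, function(s) feature_name(s$group, s$subfeature_id),
           character(1), USE.NAMES = FALSE)
  }
  if (task == "nonmedical") {
    c(nm("personal_noun"), nm("nonmedical"), nm("medical"),
      "sentiment", "url")
  } else {
    c(nm("personal_noun"), nm("side_effect"), "sentiment", "url")
  }
}

# feature group -> member columns, for ablation
feature_groups <- function(task, registry = load_default_lexicons()) {
  task <- match.arg(task, c("nonmedical", "side_effects"))
  nm <- function(g) {
    subs <- Filter(function(s) s$group == g, registry$subfeatures)
    vapply(subs, function(s) feature_name(s$group, s$subfeature_id),
           character(1), USE.NAMES = FALSE)
  }
  if (task == "nonmedical") {
    list(nonmedical_use_terms = nm("nonmedical"),
         medical_use_terms = nm("medical"),
         personal_noun = nm("personal_noun"),
         sentiment_scores = "sentiment",
         url = "url")
  } else {
    list(side_effect_terms = nm("side_effect"),
         personal_noun = nm("personal_noun"),
         sentiment_scores = "sentiment",
         url = "url")
  }
}

#' Select a task's feature columns
#'
#' @param features a named feature vector from [extract_features()] or a
#'   data frame from [featurize_corpus()].
#' @param task `"nonmedical"` or `"side_effects"`.
#' @param registry a `lexicon_registry`.
#' @return numeric vector (for a single feature vector) or numeric matrix
#'   (rows = tweets) in the order of [feature_order()].
#' @export
select_task_features <- function(features, task,
                                 registry = load_default_lexicons()) {
  cols <- feature_order(task, registry)
  if (is.data.frame(features)) {
    missing <- setdiff(cols, names(features))
    if (length(missing) > 0L) {
      stop("feature columns missing: ", paste(missing, collapse = ", "))
    }
    m <- as.matrix(features[, cols, drop = FALSE])
    rownames(m) <- if ("tweet_id" %in% names(features))
      features$tweet_id else NULL
    return(m)
  }
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0L) {
    stop("feature fields missing: ", paste(missing, collapse = ", "))
  }
  features[cols]
}

#' Featurize a corpus
#'
#' Runs tokenization and feature extraction over a corpus data frame.
#'
#' @inheritParams tokenize_corpus
#' @param registry a `lexicon_registry`.
#' @param sentiment a `sentiment_lexicon`.
#' @return data frame: `tweet_id`, `created_at` (if present), gold label
#'   columns (if present), then the 23 feature columns.
#' @export
featurize_corpus <- function(tweets, registry = load_default_lexicons(),
                             sentiment = load_sentiment_lexicon(),
                             stopwords = default_stopwords()) {
  toks <- tokenize_corpus(tweets, stopwords)
  mat <- do.call(rbind, lapply(toks, extract_features,
                               registry = registry, sentiment = sentiment))
  out <- data.frame(tweet_id = tweets$tweet_id, stringsAsFactors = FALSE)
  for (col in c("created_at", "gold_nonmedical", "gold_side_effects")) {
    if (col %in% names(tweets)) out[[col]] <- tweets[[col]]
  }
  cbind(out, as.data.frame(mat))
}

#' Write / read a featurized corpus as CSV
#'
#' One row per tweet; columns are ids, any gold labels, then the feature
#' columns in documented order.
#'
#' @param features data frame from [featurize_corpus()].
#' @param path CSV file path.
#' @return `path` invisibly (write); data frame (read).
#' @export
write_features_csv <- function(features, path) {
  df <- features
  if ("created_at" %in% names(df)) {
    df$created_at <- format(df$created_at, "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("created_at" %in% names(df)) {
    df$created_at <- as.POSIXct(df$created_at, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%SZ")
  }
  df
}
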