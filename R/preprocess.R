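# Text normalization: raw token stage (lowercase, URL stripping, apostrophes
# kept so pronoun contractions stay matchable) and content stage (numbers,
# punctuation and stop words removed, Porter stems).

URL_REGEX <- "(https?://[^[:space:]]+)|(\\bwww\\.[^[:space:]]+)|(\\bt\\.co/[^[:space:]]+)"

#' Detect a URL in tweet text
#'
#' Flags `http(s)://...`, `www....` and `t.co/...` substrings. URLs in
#' tweets usually point at news or study results rather than first-hand
#' experience, so their presence is used as a model feature.
#'
#' @param text character vector.
#' @return integer vector of 0/1 flags.
#' @examples
#' detect_url(c("see https://t.co/abc", "no links here"))
#' @export
detect_url <- function(text) {
  as.integer(grepl(URL_REGEX, text, ignore.case = TRUE))
}

#' Packaged English stop-word list
#'
#' Returns the versioned snowball-style stop-word list shipped with the
#' package (174 entries), used by [to_content_stems()]. Packaging the list
#' keeps results stable across environments.
#'
#' @return character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords-en.txt", package = "stimtweet")
  read_word_list(path)
}

#' Tokenize tweet text (raw stage)
#'
#' Lowercases, removes URLs (recording their presence), strips `#` from
#' hashtags and the `@` sigil from mentions, and splits on non-word
#' boundaries while keeping internal apostrophes, so contractions like
#' `"i'm"` survive as single tokens for personal-noun matching.
#'
#' @param text a single tweet text (nonempty after whitespace trim).
#' @param tweet_id optional identifier carried through.
#' @return object of class `tokenized_tweet`: list with `tweet_id`,
#'   `raw_tokens`, `has_url`.
#' @examples
#' tokenize("Time to pop the Ritalin I been keeping")$raw_tokens
#' @export
tokenize <- function(text, tweet_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) {
    stop("tweet text is empty after whitespace trim")
  }
  has_url <- detect_url(text)
  x <- tolower(text)
  x <- gsub(URL_REGEX, " ", x)
  x <- gsub("#(\\w)", "\\1", x)   # hashtag words carry content
  x <- gsub("@(\\w)", "\\1", x)   # keep handle text, drop sigil
  tokens <- strsplit(x, "[^a-z0-9']+")[[1]]
  tokens <- gsub("^'+|'+$", "", tokens)  # trim quote apostrophes
  tokens <- tokens[nzchar(tokens)]
  structure(
    list(tweet_id = tweet_id, raw_tokens = tokens, has_url = has_url),
    class = "tokenized_tweet"
  )
}

#' Content stems from raw tokens
#'
#' Drops stop words and purely numeric tokens, strips apostrophes, and
#' Porter-stems what remains, preserving order. Lexicon-term matching runs
#' on this stage; personal-noun matching runs on the raw tokens because
#' pronouns are stop words.
#'
#' @param raw_tokens character vector from [tokenize()].
#' @param stopwords character vector; defaults to [default_stopwords()].
#' @return character vector of stems (length <= length(raw_tokens)).
#' @examples
#' to_content_stems(c("i", "snorted", "my", "concerta"))
#' @export
to_content_stems <- function(raw_tokens, stopwords = default_stopwords()) {
  stopifnot(is.character(raw_tokens))
  keep <- !(raw_tokens %in% stopwords) & !grepl("^[0-9]+$", raw_tokens)
  tokens <- raw_tokens[keep]
  tokens <- gsub("'", "", tokens, fixed = TRUE)
  tokens <- tokens[nzchar(tokens)]
  porter_stem(tokens)
}

#' Tokenize a whole corpus
#'
#' Applies [tokenize()] and [to_content_stems()] to every tweet of a corpus
#' data frame.
#'
#' @param tweets a corpus data frame (see [read_corpus_jsonl()]): columns
#'   `tweet_id`, `text`, and optionally `created_at` and gold labels.
#' @param stopwords stop-word list for the content stage.
#' @return list of `tokenized_tweet` objects, each with an added
#'   `content_stems` element.
#' @export
tokenize_corpus <- function(tweets, stopwords = default_stopwords()) {
  stopifnot(is.data.frame(tweets), all(c("tweet_id", "text") %in%
                                         names(tweets)))
  lapply(seq_len(nrow(tweets)), function(i) {
    tt <- tokenize(tweets$text[i], tweet_id = tweets$tweet_id[i])
    tt$content_stems <- to_content_stems(tt$raw_tokens, stopwords)
    tt
  })
}

#' Term-document matrix of stem counts
#'
#' Builds the sparse terms-by-documents count matrix from per-document stem
#' lists; entry (t, d) is the count of stem t in document d, so column sums
#' equal document lengths.
#'
#' @param stem_lists list of character vectors (one per document).
#' @param doc_ids optional document names; defaults to `doc1..docN`.
#' @return a `dgCMatrix` (terms x documents) with dimnames.
#' @export
term_document_matrix <- function(stem_lists, doc_ids = NULL) {
  stopifnot(is.list(stem_lists), length(stem_lists) > 0L)
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_along(stem_lists))
  stopifnot(length(doc_ids) == length(stem_lists))
  terms <- sort(unique(unlist(stem_lists, use.names = FALSE)))
  if (length(terms) == 0L) {
    return(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(0L, length(stem_lists)),
      dimnames = list(character(0), doc_ids)
    ))
  }
  ij <- do.call(rbind, lapply(seq_along(stem_lists), function(d) {
    stems <- stem_lists[[d]]
    if (length(stems) == 0L) return(NULL)
    cbind(i = match(stems, terms), j = d)
  }))
  Matrix::sparseMatrix(
    i = ij[, "i"], j = ij[, "j"], x = rep(1, nrow(ij)),
    dims = c(length(terms), length(stem_lists)),
    dimnames = list(terms, doc_ids)
  )
}
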