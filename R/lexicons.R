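# Feature lexicons: four groups of subfeature word lists used to build the
# supervised-learning features, plus the opinion lexicon for sentiment.

LEXICON_GROUPS <- c("personal_noun", "nonmedical", "medical", "side_effect")

# expected subfeature count per group in the packaged registry
LEXICON_GROUP_SIZES <- c(
  personal_noun = 4L, nonmedical = 7L, medical = 1L, side_effect = 9L
)

#' Load a feature-lexicon registry from a JSON file
#'
#' The registry file maps feature groups (`personal_noun`, `nonmedical`,
#' `medical`, `side_effect`) to subfeatures, each holding a set of lowercase
#' match stems and a match mode. Stems ending in an apostrophe (e.g. `"i'"`,
#' `"he'"`) are matched as raw-token prefixes, so `"i'm"` and `"he's"` hit
#' the truncated forms; all other stems match by equality.
#'
#' @param path path to a registry JSON file; defaults to the packaged
#'   registry of curated methylphenidate lexicons.
#' @return an object of class `lexicon_registry`: a list with `version` and
#'   `subfeatures` (a list of `subfeature_lexicon` entries with fields
#'   `group`, `subfeature_id`, `match_mode`, `stems`).
#' @seealso [validate_registry()], [extract_features()]
#' @export
load_lexicons <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lexicons.json", package = "stimtweet")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("lexicon registry file not found: ", path)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$groups) || is.null(raw$version)) {
    stop("malformed lexicon file (missing 'groups' or 'version'): ", path)
  }
  subfeatures <- list()
  for (group in names(raw$groups)) {
    if (!group %in% LEXICON_GROUPS) {
      stop("malformed lexicon file: unknown group '", group, "'")
    }
    for (sub_id in names(raw$groups[[group]])) {
      entry <- raw$groups[[group]][[sub_id]]
      stems <- unlist(entry$stems, use.names = FALSE)
      mode <- entry$match_mode
      if (is.null(stems) || length(stems) == 0L) {
        stop("malformed lexicon file: empty stems in '", group, "/",
             sub_id, "'")
      }
      if (is.null(mode) || !mode %in% c("exact_stem", "raw_prefix")) {
        stop("malformed lexicon file: bad match_mode in '", group, "/",
             sub_id, "'")
      }
      sub <- structure(
        list(group = group, subfeature_id = sub_id,
             match_mode = mode, stems = as.character(stems)),
        class = "subfeature_lexicon"
      )
      subfeatures[[paste(group, sub_id, sep = ".")]] <- sub
    }
  }
  reg <- structure(
    list(version = raw$version, subfeatures = subfeatures),
    class = "lexicon_registry"
  )
  issues <- validate_registry(reg)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    stop("invalid lexicon registry '", path, "': ",
         paste(errs$message, collapse = "; "))
  }
  reg
}

#' Load the packaged default lexicon registry
#'
#' Returns the curated default registry: 4 personal-noun subfeatures,
#' 7 nonmedical-use subfeatures, 1 medical-use subfeature and 9 side-effect
#' subfeatures, including nonstandard spellings common on Twitter
#' ("im", "iam", "ur") and pre-stemmed entries ("abus", "studi").
#'
#' @return a `lexicon_registry`, see [load_lexicons()].
#' @examples
#' reg <- load_default_lexicons()
#' reg$subfeatures[["nonmedical.overdose"]]$stems
#' @export
load_default_lexicons <- function() {
  reg <- load_lexicons()
  counts <- table(vapply(reg$subfeatures, `[[`, "", "group"))
  for (g in names(LEXICON_GROUP_SIZES)) {
    if (is.na(counts[g]) || counts[g] != LEXICON_GROUP_SIZES[g]) {
      stop("packaged registry must have ", LEXICON_GROUP_SIZES[g], " '", g,
           "' subfeatures, found ", ifelse(is.na(counts[g]), 0L, counts[g]))
    }
  }
  reg
}

#' Validate a lexicon registry
#'
#' Report-only check: flags empty subfeatures, stems that are not lowercase
#' or contain whitespace, duplicate stems within a subfeature, and stems
#' duplicated across subfeatures of the same group.
#'
#' @param reg a `lexicon_registry`.
#' @return data.frame with columns `severity` ("error"/"warning"), `group`,
#'   `subfeature`, `message`; zero rows for a valid registry.
#' @export
validate_registry <- function(reg) {
  stopifnot(inherits(reg, "lexicon_registry"))
  issues <- list()
  add <- function(severity, group, sub, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, group = group, subfeature = sub,
      message = message, stringsAsFactors = FALSE
    )
  }
  for (sub in reg$subfeatures) {
    if (length(sub$stems) == 0L) {
      add("error", sub$group, sub$subfeature_id, sprintf(
        "subfeature '%s/%s' has no stems", sub$group, sub$subfeature_id))
      next
    }
    bad_case <- sub$stems[sub$stems != tolower(sub$stems)]
    if (length(bad_case) > 0L) {
      add("error", sub$group, sub$subfeature_id, sprintf(
        "non-lowercase stems in '%s/%s': %s", sub$group, sub$subfeature_id,
        paste(bad_case, collapse = ", ")))
    }
    ws <- sub$stems[grepl("[[:space:]]", sub$stems)]
    if (length(ws) > 0L) {
      add("error", sub$group, sub$subfeature_id, sprintf(
        "whitespace inside stems in '%s/%s': %s", sub$group,
        sub$subfeature_id, paste(ws, collapse = ", ")))
    }
    dup <- unique(sub$stems[duplicated(sub$stems)])
    if (length(dup) > 0L) {
      add("error", sub$group, sub$subfeature_id, sprintf(
        "duplicate stems within '%s/%s': %s", sub$group, sub$subfeature_id,
        paste(dup, collapse = ", ")))
    }
  }
  # cross-subfeature duplicates within one group
  for (g in LEXICON_GROUPS) {
    subs <- Filter(function(s) s$group == g, reg$subfeatures)
    if (length(subs) < 2L) next
    stem_tab <- table(unlist(lapply(subs, function(s) unique(s$stems))))
    shared <- names(stem_tab)[stem_tab > 1L]
    for (stem in shared) {
      where <- vapply(subs, function(s) stem %in% s$stems, logical(1))
      add("warning", g, NA_character_, sprintf(
        "stem '%s' appears in multiple '%s' subfeatures: %s", stem, g,
        paste(vapply(subs[where], `[[`, "", "subfeature_id"),
              collapse = ", ")))
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(severity = character(0), group = character(0),
                      subfeature = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Serialize a lexicon registry to JSON
#'
#' Writes the same schema [load_lexicons()] reads, so a registry round-trips.
#'
#' @param reg a `lexicon_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicons <- function(reg, path) {
  stopifnot(inherits(reg, "lexicon_registry"))
  groups <- list()
  for (sub in reg$subfeatures) {
    groups[[sub$group]][[sub$subfeature_id]] <- list(
      match_mode = sub$match_mode, stems = sub$stems
    )
  }
  jsonlite::write_json(list(version = reg$version, groups = groups), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.lexicon_registry <- function(x, ...) {
  counts <- table(vapply(x$subfeatures, `[[`, "", "group"))
  n_stems <- sum(vapply(x$subfeatures, function(s) length(s$stems),
                        integer(1)))
  cat("Lexicon registry (version ", x$version, ")\n", sep = "")
  cat("  ", length(x$subfeatures), " subfeatures, ", n_stems,
      " stems total\n", sep = "")
  for (g in names(counts)) {
    cat(sprintf("  %-14s %d subfeatures\n", g, counts[[g]]))
  }
  invisible(x)
}

#' Load an opinion lexicon for sentiment scoring
#'
#' Reads two plain-text word lists (one word per line, lines starting with
#' `;` or `#` skipped) into positive and negative word sets, then applies
#' user additions. An addition overrides list membership: the word is moved
#' to the stated polarity.
#'
#' @param positive_path,negative_path paths to word-list files; defaults are
#'   the packaged opinion-lexicon subsets.
#' @param additions named character vector `c(word = polarity, ...)` with
#'   polarity `"positive"` or `"negative"`; the default adds "wtf" as a
#'   negative word, reflecting Twitter usage missing from standard lists.
#' @return object of class `sentiment_lexicon` with elements `positive`
#'   and `negative` (character vectors) and `additions`.
#' @examples
#' lex <- load_sentiment_lexicon()
#' "wtf" %in% lex$negative
#' @export
load_sentiment_lexicon <- function(positive_path = NULL,
                                   negative_path = NULL,
                                   additions = c(wtf = "negative")) {
  if (is.null(positive_path)) {
    positive_path <- system.file("extdata", "sentiment-positive-subset.txt",
                                 package = "stimtweet")
  }
  if (is.null(negative_path)) {
    negative_path <- system.file("extdata", "sentiment-negative-subset.txt",
                                 package = "stimtweet")
  }
  pos <- read_word_list(positive_path)
  neg <- read_word_list(negative_path)
  if (length(additions) > 0L) {
    if (is.null(names(additions)) || any(!nzchar(names(additions)))) {
      stop("'additions' must be a named vector: c(word = polarity)")
    }
    if (any(!additions %in% c("positive", "negative"))) {
      stop("addition polarities must be 'positive' or 'negative'")
    }
    for (word in names(additions)) {
      w <- tolower(word)
      pos <- setdiff(pos, w)
      neg <- setdiff(neg, w)
      if (additions[[word]] == "positive") pos <- c(pos, w) else
        neg <- c(neg, w)
    }
  }
  clash <- intersect(pos, neg)
  if (length(clash) > 0L) {
    stop("word(s) present in both polarity sets: ",
         paste(clash, collapse = ", "))
  }
  structure(
    list(positive = sort(unique(pos)), negative = sort(unique(neg)),
         additions = additions),
    class = "sentiment_lexicon"
  )
}

read_word_list <- function(path) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("word-list file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";") &
                   !startsWith(lines, "#")]
  tolower(lines)
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat("Sentiment lexicon: ", length(x$positive), " positive / ",
      length(x$negative), " negative words (",
      length(x$additions), " user additions)\n", sep = "")
  invisible(x)
}
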