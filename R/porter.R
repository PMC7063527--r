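# Porter stemming algorithm (Porter 1980), implemented for lexicon matching.
# Operates on lowercase words; words shorter than 3 characters and tokens
# containing characters outside a-z are returned unchanged.

#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter algorithm,
#' so that inflected forms ("snorted", "snorting") collapse onto the stems
#' used by the feature lexicons ("snort").
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("snorted", "studying", "abuse", "parties"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(word) {
  if (is.na(word) || nchar(word) < 3L || grepl("[^a-z]", word)) {
    return(word)
  }
  w <- strsplit(word, "", fixed = TRUE)[[1]]
  w <- pt_step1a(w)
  w <- pt_step1b(w)
  w <- pt_step1c(w)
  w <- pt_step2(w)
  w <- pt_step3(w)
  w <- pt_step4(w)
  w <- pt_step5a(w)
  w <- pt_step5b(w)
  paste(w, collapse = "")
}

# consonant/vowel classification; y is a vowel iff preceded by a consonant
pt_is_cons <- function(w, i) {
  ch <- w[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!pt_is_cons(w, i - 1L))
  }
  TRUE
}

# the measure m: number of VC blocks in [C](VC)^m[V]
pt_measure <- function(w) {
  n <- length(w)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) pt_is_cons(w, i), logical(1))
  runs <- rle(types)$values
  if (runs[1L]) runs <- runs[-1L]  # drop leading consonant run
  # pattern now alternates V,C,V,C,...; m = number of complete VC pairs
  if (length(runs) == 0L) return(0L)
  floor(length(runs) / 2)
}

pt_has_vowel <- function(w) {
  n <- length(w)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) pt_is_cons(w, i), logical(1)))
}

pt_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[n] == w[n - 1L] && pt_is_cons(w, n)
}

# *o: stem ends cvc where the final consonant is not w, x or y
pt_cvc <- function(w) {
  n <- length(w)
  n >= 3L &&
    pt_is_cons(w, n) && !pt_is_cons(w, n - 1L) && pt_is_cons(w, n - 2L) &&
    !(w[n] %in% c("w", "x", "y"))
}

pt_ends <- function(w, suffix) {
  s <- strsplit(suffix, "", fixed = TRUE)[[1]]
  n <- length(w); k <- length(s)
  n >= k && all(w[(n - k + 1L):n] == s)
}

pt_chop <- function(w, k) if (k >= length(w)) character(0) else w[seq_len(length(w) - k)]

pt_append <- function(w, suffix) c(w, strsplit(suffix, "", fixed = TRUE)[[1]])

pt_step1a <- function(w) {
  if (pt_ends(w, "sses")) return(pt_chop(w, 2L))
  if (pt_ends(w, "ies")) return(pt_chop(w, 2L))
  if (pt_ends(w, "ss")) return(w)
  if (pt_ends(w, "s")) return(pt_chop(w, 1L))
  w
}

pt_step1b <- function(w) {
  if (pt_ends(w, "eed")) {
    if (pt_measure(pt_chop(w, 3L)) > 0L) return(pt_chop(w, 1L))
    return(w)
  }
  removed <- FALSE
  if (pt_ends(w, "ed") && pt_has_vowel(pt_chop(w, 2L))) {
    w <- pt_chop(w, 2L); removed <- TRUE
  } else if (pt_ends(w, "ing") && pt_has_vowel(pt_chop(w, 3L))) {
    w <- pt_chop(w, 3L); removed <- TRUE
  }
  if (removed) {
    if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
      w <- pt_append(w, "e")
    } else if (pt_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      w <- w[-length(w)]
    } else if (pt_measure(w) == 1L && pt_cvc(w)) {
      w <- pt_append(w, "e")
    }
  }
  w
}

pt_step1c <- function(w) {
  if (pt_ends(w, "y") && pt_has_vowel(pt_chop(w, 1L))) {
    w[length(w)] <- "i"
  }
  w
}

# rule tables: condition is a minimum measure of the remaining stem
pt_apply_rules <- function(w, rules, min_m) {
  # longest matching suffix decides; its condition either fires or blocks
  ord <- order(nchar(names(rules)), decreasing = TRUE)
  for (i in ord) {
    suf <- names(rules)[i]
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, nchar(suf))
      if (pt_measure(stem) > min_m) {
        return(pt_append(stem, rules[[i]]))
      }
      return(w)
    }
  }
  w
}

pt_step2 <- function(w) {
  rules <- c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  )
  pt_apply_rules(w, as.list(rules), 0L)
}

pt_step3 <- function(w) {
  rules <- list(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  )
  pt_apply_rules(w, rules, 0L)
}

pt_step4 <- function(w) {
  sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  ord <- order(nchar(sufs), decreasing = TRUE)
  for (suf in sufs[ord]) {
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, nchar(suf))
      if (suf == "ion" &&
          !(length(stem) > 0L && stem[length(stem)] %in% c("s", "t"))) {
        return(w)
      }
      if (pt_measure(stem) > 1L) return(stem)
      return(w)
    }
  }
  w
}

pt_step5a <- function(w) {
  if (pt_ends(w, "e")) {
    stem <- pt_chop(w, 1L)
    m <- pt_measure(stem)
    if (m > 1L || (m == 1L && !pt_cvc(stem))) return(stem)
  }
  w
}

pt_step5b <- function(w) {
  if (pt_measure(w) > 1L && pt_double_cons(w) && w[length(w)] == "l") {
    return(w[-length(w)])
  }
  w
}
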