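# Porter stemming algorithm (Porter 1980), implemented from the published
# rule tables.  Operates on lowercase ASCII words.

porter_is_cons <- function(chars) {
  # consonant flags for a word split into characters; y is a consonant when
  # it starts the word or follows a vowel-position... per Porter: y is a
  # consonant if preceded by a consonant letter is FALSE -> y after
  # consonant acts as vowel.  Computed left to right.
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) cons[i] <- FALSE
    else if (ch == "y") cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    else cons[i] <- TRUE
  }
  cons
}

# measure m: number of VC sequences in the word
porter_m <- function(word) {
  if (!nzchar(word)) return(0L)
  cons <- porter_is_cons(strsplit(word, "")[[1]])
  # collapse runs
  runs <- rle(cons)$values
  # pattern [C](VC)^m[V]
  if (length(runs) && runs[1]) runs <- runs[-1]
  if (length(runs) && !runs[length(runs)]) runs <- runs[-length(runs)]
  length(runs) %/% 2L
}

porter_has_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(!porter_is_cons(strsplit(word, "")[[1]]))
}

porter_ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L); b <- substr(word, n, n)
  if (a != b) return(FALSE)
  cons <- porter_is_cons(strsplit(word, "")[[1]])
  cons[n]
}

# *o: stem ends cvc where the final c is not w, x or y
porter_ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- porter_is_cons(strsplit(word, "")[[1]])
  last <- substr(word, n, n)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(last %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  n <- nchar(word); m <- nchar(suffix)
  n > m && substr(word, n - m + 1L, n) == suffix
}

porter_stem_word <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- word

  # Step 1a
  if (porter_ends(w, "sses")) w <- substr(w, 1, nchar(w) - 2L)
  else if (porter_ends(w, "ies")) w <- substr(w, 1, nchar(w) - 2L)
  else if (porter_ends(w, "ss")) w <- w
  else if (porter_ends(w, "s")) w <- substr(w, 1, nchar(w) - 1L)

  # Step 1b
  flag1b <- FALSE
  if (porter_ends(w, "eed")) {
    stem <- substr(w, 1, nchar(w) - 3L)
    if (porter_m(stem) > 0L) w <- substr(w, 1, nchar(w) - 1L)
  } else if (porter_ends(w, "ed")) {
    stem <- substr(w, 1, nchar(w) - 2L)
    if (porter_has_vowel(stem)) { w <- stem; flag1b <- TRUE }
  } else if (porter_ends(w, "ing")) {
    stem <- substr(w, 1, nchar(w) - 3L)
    if (porter_has_vowel(stem)) { w <- stem; flag1b <- TRUE }
  }
  if (flag1b) {
    if (porter_ends(w, "at") || porter_ends(w, "bl") || porter_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porter_ends_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- substr(w, 1, nchar(w) - 1L)
    } else if (porter_m(w) == 1L && porter_ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # Step 1c
  if (porter_ends(w, "y") && porter_has_vowel(substr(w, 1, nchar(w) - 1L)))
    w <- paste0(substr(w, 1, nchar(w) - 1L), "i")

  # Step 2 (condition m(stem) > 0)
  step2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent",
             eli = "e", ousli = "ous", ization = "ize", ation = "ate",
             ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
             ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(step2)) {
    if (porter_ends(w, suf)) {
      stem <- substr(w, 1, nchar(w) - nchar(suf))
      if (porter_m(stem) > 0L) w <- paste0(stem, step2[[suf]])
      break
    }
  }

  # Step 3 (condition m(stem) > 0)
  step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  for (suf in names(step3)) {
    if (porter_ends(w, suf)) {
      stem <- substr(w, 1, nchar(w) - nchar(suf))
      if (porter_m(stem) > 0L) w <- paste0(stem, step3[[suf]])
      break
    }
  }

  # Step 4 (condition m(stem) > 1)
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  for (suf in step4) {
    if (porter_ends(w, suf)) {
      stem <- substr(w, 1, nchar(w) - nchar(suf))
      ok <- porter_m(stem) > 1L
      if (suf == "ion")
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      if (ok) w <- stem
      break
    }
  }

  # Step 5a
  if (porter_ends(w, "e")) {
    stem <- substr(w, 1, nchar(w) - 1L)
    m <- porter_m(stem)
    if (m > 1L || (m == 1L && !porter_ends_cvc(stem))) w <- stem
  }
  # Step 5b
  if (porter_m(w) > 1L && porter_ends_double_cons(w) &&
      porter_ends(w, "l"))
    w <- substr(w, 1, nchar(w) - 1L)

  w
}

#' Porter stem a vector of words
#'
#' Pure-R implementation of the Porter (1980) suffix-stripping algorithm for
#' English.  Input is expected lowercase; stemming is applied per unique
#' word and mapped back, so repeated tokens are cheap.
#'
#' @param words character vector of lowercase words.
#' @return Character vector of stems, same length and order.
#' @examples
#' porter_stem(c("trees", "protected", "pollution", "running"))
#' @export
porter_stem <- function(words) {
  if (!length(words)) return(character(0))
  u <- unique(words)
  stems <- vapply(u, porter_stem_word, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}
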