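# Snowball English ("Porter2") stemmer.
#
# Implemented from the published algorithm definition: R1/R2 regions,
# consonant-y marking, steps 0-5 with the standard exceptional forms.
# Results are cached per session because corpora repeat tokens heavily.

.sb_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.sb_li_end <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.sb_exceptions1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.sb_exceptions2 <- c(
  "inning", "outing", "canning", "herring", "earring",
  "proceed", "exceed", "succeed"
)

# vowels after consonant-y marking: "y" left lowercase is a vowel, "Y" is not
.sb_is_v <- function(chs) chs %in% c("a", "e", "i", "o", "u", "y")

# start of the region after the first non-vowel that follows a vowel,
# scanning pairs (j-1, j) with j-1 >= from; length(ch)+1 when absent
.sb_region_after <- function(ch, from) {
  n <- length(ch)
  j <- from + 1L
  while (j <= n) {
    if (!.sb_is_v(ch[j]) && .sb_is_v(ch[j - 1L])) return(j + 1L)
    j <- j + 1L
  }
  n + 1L
}

.sb_ends_short_syllable <- function(ch) {
  n <- length(ch)
  if (n == 2L) return(.sb_is_v(ch[1L]) && !.sb_is_v(ch[2L]))
  if (n >= 3L) {
    return(!.sb_is_v(ch[n - 2L]) && .sb_is_v(ch[n - 1L]) &&
             !.sb_is_v(ch[n]) && !(ch[n] %in% c("w", "x", "Y")))
  }
  FALSE
}

.sb_ends <- function(w, suf) {
  nw <- nchar(w)
  ns <- nchar(suf)
  nw >= ns && substring(w, nw - ns + 1L) == suf
}

# is the suffix (known to match) inside the region starting at p?
.sb_in <- function(w, suf, p) nchar(w) - nchar(suf) + 1L >= p

.sb_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

.porter2_one <- function(word) {
  w <- word
  if (nchar(w) <= 2L) return(w)
  w <- sub("^'", "", w)

  if (w %in% names(.sb_exceptions1)) return(unname(.sb_exceptions1[w]))
  if (nchar(w) <= 2L) return(w)

  # mark y's that function as consonants
  ch <- .sb_chars(w)
  for (k in seq_along(ch)) {
    if (ch[k] == "y" && (k == 1L || .sb_is_v(ch[k - 1L]))) ch[k] <- "Y"
  }
  w <- paste(ch, collapse = "")

  n <- length(ch)
  p1 <- if (startsWith(w, "gener")) 6L
  else if (startsWith(w, "commun")) 7L
  else if (startsWith(w, "arsen")) 6L
  else .sb_region_after(ch, 1L)
  p2 <- .sb_region_after(ch, p1)

  # --- step 0: strip apostrophe suffixes
  for (suf in c("'s'", "'s", "'")) {
    if (.sb_ends(w, suf)) {
      w <- substring(w, 1L, nchar(w) - nchar(suf))
      break
    }
  }

  # --- step 1a
  if (.sb_ends(w, "sses")) {
    w <- paste0(substring(w, 1L, nchar(w) - 4L), "ss")
  } else if (.sb_ends(w, "ied") || .sb_ends(w, "ies")) {
    stem <- substring(w, 1L, nchar(w) - 3L)
    w <- paste0(stem, if (nchar(stem) > 1L) "i" else "ie")
  } else if (.sb_ends(w, "ss") || .sb_ends(w, "us")) {
    # leave unchanged
  } else if (.sb_ends(w, "s")) {
    pre <- .sb_chars(substring(w, 1L, nchar(w) - 1L))
    if (length(pre) >= 2L && any(.sb_is_v(pre[seq_len(length(pre) - 1L)]))) {
      w <- substring(w, 1L, nchar(w) - 1L)
    }
  }

  if (w %in% .sb_exceptions2) return(w)

  # --- step 1b
  s1b <- c("eedly", "ingly", "edly", "eed", "ing", "ed")
  for (suf in s1b) {
    if (!.sb_ends(w, suf)) next
    if (suf %in% c("eed", "eedly")) {
      if (.sb_in(w, suf, p1)) {
        w <- paste0(substring(w, 1L, nchar(w) - nchar(suf)), "ee")
      }
    } else {
      pre <- substring(w, 1L, nchar(w) - nchar(suf))
      if (any(.sb_is_v(.sb_chars(pre)))) {
        w <- pre
        if (.sb_ends(w, "at") || .sb_ends(w, "bl") || .sb_ends(w, "iz")) {
          w <- paste0(w, "e")
        } else if (any(vapply(.sb_doubles, function(d) .sb_ends(w, d),
                              logical(1)))) {
          w <- substring(w, 1L, nchar(w) - 1L)
        } else {
          wc <- .sb_chars(w)
          if (p1 > length(wc) && .sb_ends_short_syllable(wc)) {
            w <- paste0(w, "e")
          }
        }
      }
    }
    break
  }

  # --- step 1c: y -> i after a non-vowel that is not the first letter
  nw <- nchar(w)
  if (nw >= 3L && substring(w, nw) %in% c("y", "Y")) {
    prev <- substring(w, nw - 1L, nw - 1L)
    if (!.sb_is_v(prev)) {
      w <- paste0(substring(w, 1L, nw - 1L), "i")
    }
  }

  # --- step 2 (longest match; apply only if suffix in R1)
  s2 <- list(
    ational = "ate", fulness = "ful", iveness = "ive", ization = "ize",
    ousness = "ous", biliti = "ble", lessli = "less", tional = "tion",
    ation = "ate", alism = "al", aliti = "al", entli = "ent", fulli = "ful",
    ousli = "ous", anci = "ance", abli = "able", alli = "al", ator = "ate",
    enci = "ence", izer = "ize", iviti = "ive", bli = "ble", ogi = "og",
    li = ""
  )
  s2names <- names(s2)[order(-nchar(names(s2)))]
  for (suf in s2names) {
    if (!.sb_ends(w, suf)) next
    if (.sb_in(w, suf, p1)) {
      pre <- substring(w, 1L, nchar(w) - nchar(suf))
      if (suf == "ogi") {
        if (.sb_ends(pre, "l")) w <- paste0(pre, "og")
      } else if (suf == "li") {
        if (nchar(pre) >= 1L && substring(pre, nchar(pre)) %in% .sb_li_end) {
          w <- pre
        }
      } else {
        w <- paste0(pre, s2[[suf]])
      }
    }
    break
  }

  # --- step 3 (in R1; "ative" needs R2)
  s3 <- list(
    ational = "ate", tional = "tion", alize = "al", icate = "ic",
    iciti = "ic", ative = "", ical = "ic", ness = "", ful = ""
  )
  s3names <- names(s3)[order(-nchar(names(s3)))]
  for (suf in s3names) {
    if (!.sb_ends(w, suf)) next
    if (.sb_in(w, suf, p1)) {
      if (suf == "ative") {
        if (.sb_in(w, suf, p2)) w <- substring(w, 1L, nchar(w) - 5L)
      } else {
        w <- paste0(substring(w, 1L, nchar(w) - nchar(suf)), s3[[suf]])
      }
    }
    break
  }

  # --- step 4 (delete if in R2; "ion" also needs preceding s/t)
  s4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
          "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic")
  for (suf in s4) {
    if (!.sb_ends(w, suf)) next
    if (.sb_in(w, suf, p2)) {
      pre <- substring(w, 1L, nchar(w) - nchar(suf))
      if (suf == "ion") {
        if (.sb_ends(pre, "s") || .sb_ends(pre, "t")) w <- pre
      } else {
        w <- pre
      }
    }
    break
  }

  # --- step 5
  nw <- nchar(w)
  if (nw >= 1L && substring(w, nw) == "e") {
    if (nw >= p2) {
      w <- substring(w, 1L, nw - 1L)
    } else if (nw >= p1) {
      pre <- .sb_chars(substring(w, 1L, nw - 1L))
      if (!.sb_ends_short_syllable(pre)) w <- substring(w, 1L, nw - 1L)
    }
  } else if (nw >= 2L && substring(w, nw) == "l" && nw >= p2 &&
             substring(w, nw - 1L, nw - 1L) == "l") {
    w <- substring(w, 1L, nw - 1L)
  }

  chartr("Y", "y", w)
}

.sb_cache <- new.env(parent = emptyenv())

#' Stem tokens with the Snowball English stemmer
#'
#' Applies the Snowball (Porter2) English stemming algorithm to a character
#' vector of lowercase tokens. This is the stemmer the whole pipeline uses:
#' corpus preprocessing, ground-truth term normalization and lexical-resource
#' lemma insertion all stem through this one function, so stemmed surfaces
#' unify across the three sources.
#'
#' @param words Character vector of tokens (assumed lowercase; uppercase
#'   input is lowered first).
#' @return Character vector of stems, same length as `words`.
#' @examples
#' snowball_stem(c("fatigue", "fatigues", "fatigued", "fatiguing"))
#' snowball_stem("headaches")
#' @export
snowball_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  stopifnot(is.character(words))
  words <- tolower(words)
  uniq <- unique(words)
  miss <- uniq[!vapply(uniq, exists, logical(1), envir = .sb_cache,
                       inherits = FALSE)]
  for (wd in miss) {
    assign(wd, .porter2_one(wd), envir = .sb_cache)
  }
  out <- vapply(words, get, character(1), envir = .sb_cache,
                inherits = FALSE)
  names(out) <- NULL
  out
}

# Available stemmers; kept as a registry so configuration errors are caught
# early and the stemmer choice can be recorded in provenance output.
.stemmers <- list("snowball-english" = snowball_stem)

#' Resolve a stemmer identifier
#'
#' @param stemmer_id Identifier string; currently `"snowball-english"`.
#' @return The stemming function (character vector in, character vector out).
#' @export
get_stemmer <- function(stemmer_id = "snowball-english") {
  fn <- .stemmers[[stemmer_id]]
  if (is.null(fn)) {
    stop("unknown stemmer_id: '", stemmer_id, "' (available: ",
         paste(names(.stemmers), collapse = ", "), ")", call. = FALSE)
  }
  fn
}
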