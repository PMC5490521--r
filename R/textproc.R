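# Linguistic preprocessing for short food names: normalization, tokenization,
# Porter stemming, rule-based Penn-style POS tagging, and lemmatization.
# Food names are almost always noun phrases, so the tagger defaults to noun
# and uses morphology plus small domain lexicons for verbs and adjectives.

#' Normalize a food name for the document-term matrix
#'
#' Lowercases, removes punctuation and digits, and collapses whitespace.
#'
#' @param name A character vector of food names.
#' @return A character vector of the same length; empty input maps to "".
#' @examples
#' preprocess_name("dried vine fruits (raisins etc.)")
#' preprocess_name("Cow milk, <1% fat (skimmed milk)")
#' @export
preprocess_name <- function(name) {
  x <- tolower(as.character(name))
  x <- gsub("[^a-z]+", " ", x)
  x <- gsub("[ ]+", " ", x)
  trimws(x)
}

#' Tokenize a preprocessed name
#'
#' @param text A preprocessed string (see [preprocess_name()]).
#' @return Character vector of whitespace-delimited tokens, order preserved;
#'   empty string gives `character(0)`.
#' @examples
#' tokenize_name("dried vine fruits raisins etc")
#' @export
tokenize_name <- function(text) {
  stopifnot(length(text) == 1L)
  if (!nzchar(trimws(text))) return(character(0))
  strsplit(trimws(text), "[ ]+")[[1L]]
}

# word tokens of the raw (unpreprocessed) name, for POS tagging
word_tokens <- function(name) {
  m <- gregexpr("[a-z]+", tolower(as.character(name)))
  tok <- regmatches(tolower(as.character(name)), m)[[1L]]
  tok[nzchar(tok)]
}

## ---------------------------------------------------------------------------
## Porter stemmer

porter_vowel <- function(letters, i) {
  l <- letters[i]
  if (l %in% c("a", "e", "i", "o", "u")) return(TRUE)
  # y counts as a vowel when preceded by a consonant
  if (l == "y" && i > 1L && !porter_vowel(letters, i - 1L)) return(TRUE)
  FALSE
}

porter_shape <- function(stem) {
  # vector of "v"/"c" for each letter
  letters <- strsplit(stem, "")[[1L]]
  if (!length(letters)) return(character(0))
  vapply(seq_along(letters),
         function(i) if (porter_vowel(letters, i)) "v" else "c",
         character(1))
}

# measure m = number of vowel->consonant transitions in the shape
porter_measure <- function(stem) {
  s <- porter_shape(stem)
  if (length(s) < 2L) return(0L)
  sum(s[-length(s)] == "v" & s[-1L] == "c")
}

porter_has_vowel <- function(stem) any(porter_shape(stem) == "v")

porter_double_c <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L)
  b <- substr(stem, n, n)
  a == b && utils::tail(porter_shape(stem), 1L) == "c"
}

porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  s <- porter_shape(stem)
  last <- substr(stem, n, n)
  s[n - 2L] == "c" && s[n - 1L] == "v" && s[n] == "c" &&
    !(last %in% c("w", "x", "y"))
}

ends_with <- function(word, suffix) {
  nw <- nchar(word); ns <- nchar(suffix)
  nw >= ns && substr(word, nw - ns + 1L, nw) == suffix
}

chop <- function(word, n) substr(word, 1L, nchar(word) - n)

# apply the first (longest-suffix) matching rule of a step; rules is a list of
# c(suffix, replacement, min_m); min_m = -1 means unconditional
porter_rule_step <- function(word, rules, extra = NULL) {
  ord <- order(-nchar(vapply(rules, `[[`, character(1), 1L)))
  for (r in rules[ord]) {
    suf <- r[[1L]]
    if (ends_with(word, suf)) {
      stem <- chop(word, nchar(suf))
      min_m <- as.integer(r[[3L]])
      ok <- porter_measure(stem) > min_m
      if (!is.null(extra)) ok <- ok && extra(stem)
      if (ok) return(paste0(stem, r[[2L]]))
      return(word)  # longest match found but condition failed: step ends
    }
  }
  word
}

#' Porter stem of a single token
#'
#' Suffix-stripping approximation of the lemma used to build the
#' document-term matrix, e.g. \code{"dried"} stems to \code{"dri"} while its
#' lemma is \code{"dry"}. Words shorter than three letters are returned
#' unchanged.
#'
#' @param token A lowercase word (vectorized over a character vector).
#' @return Character vector of stems.
#' @examples
#' porter_stem(c("dried", "fruits", "raisins", "soup"))
#' @export
porter_stem <- function(token) {
  vapply(as.character(token), porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(word) {
  if (is.na(word) || nchar(word) < 3L) return(word)

  # step 1a
  if (ends_with(word, "sses")) word <- chop(word, 2L)
  else if (ends_with(word, "ies")) word <- paste0(chop(word, 3L), "i")
  else if (!ends_with(word, "ss") && ends_with(word, "s")) word <- chop(word, 1L)

  # step 1b
  step1b_applied <- FALSE
  if (ends_with(word, "eed")) {
    if (porter_measure(chop(word, 3L)) > 0L) word <- chop(word, 1L)
  } else if (ends_with(word, "ed") && porter_has_vowel(chop(word, 2L))) {
    word <- chop(word, 2L); step1b_applied <- TRUE
  } else if (ends_with(word, "ing") && porter_has_vowel(chop(word, 3L))) {
    word <- chop(word, 3L); step1b_applied <- TRUE
  }
  if (step1b_applied) {
    if (ends_with(word, "at") || ends_with(word, "bl") || ends_with(word, "iz")) {
      word <- paste0(word, "e")
    } else if (porter_double_c(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- chop(word, 1L)
    } else if (porter_measure(word) == 1L && porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (ends_with(word, "y") && porter_has_vowel(chop(word, 1L))) {
    word <- paste0(chop(word, 1L), "i")
  }

  # step 2 (m > 0)
  word <- porter_rule_step(word, list(
    c("ational", "ate", 0L), c("tional", "tion", 0L), c("enci", "ence", 0L),
    c("anci", "ance", 0L), c("izer", "ize", 0L), c("abli", "able", 0L),
    c("alli", "al", 0L), c("entli", "ent", 0L), c("eli", "e", 0L),
    c("ousli", "ous", 0L), c("ization", "ize", 0L), c("ation", "ate", 0L),
    c("ator", "ate", 0L), c("alism", "al", 0L), c("iveness", "ive", 0L),
    c("fulness", "ful", 0L), c("ousness", "ous", 0L), c("aliti", "al", 0L),
    c("iviti", "ive", 0L), c("biliti", "ble", 0L)))

  # step 3 (m > 0)
  word <- porter_rule_step(word, list(
    c("icate", "ic", 0L), c("ative", "", 0L), c("alize", "al", 0L),
    c("iciti", "ic", 0L), c("ical", "ic", 0L), c("ful", "", 0L),
    c("ness", "", 0L)))

  # step 4 (m > 1); 'ion' additionally requires the stem to end in s or t
  if (ends_with(word, "ion")) {
    stem <- chop(word, 3L)
    if (porter_measure(stem) > 1L &&
        substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
      word <- stem
    }
  } else {
    word <- porter_rule_step(word, list(
      c("al", "", 1L), c("ance", "", 1L), c("ence", "", 1L), c("er", "", 1L),
      c("ic", "", 1L), c("able", "", 1L), c("ible", "", 1L), c("ant", "", 1L),
      c("ement", "", 1L), c("ment", "", 1L), c("ent", "", 1L), c("ou", "", 1L),
      c("ism", "", 1L), c("ate", "", 1L), c("iti", "", 1L), c("ous", "", 1L),
      c("ive", "", 1L), c("ize", "", 1L)))
  }

  # step 5a
  if (ends_with(word, "e")) {
    stem <- chop(word, 1L)
    m <- porter_measure(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) word <- stem
  }
  # step 5b
  if (porter_measure(word) > 1L && porter_double_c(word) &&
      ends_with(word, "l")) {
    word <- chop(word, 1L)
  }
  word
}

## ---------------------------------------------------------------------------
## Lexicons

function_word_tags <- function() {
  c(and = "CC", or = "CC", but = "CC",
    with = "IN", without = "IN", of = "IN", "in" = "IN", on = "IN",
    "for" = "IN", from = "IN", to = "IN", at = "IN", by = "IN", per = "IN",
    as = "IN", into = "IN",
    the = "DT", a = "DT", an = "DT", its = "PRP", their = "PRP",
    etc = "FW")
}

adjective_lexicon <- function() {
  c("fresh", "raw", "sweet", "sour", "bitter", "hot", "cold", "green", "red",
    "brown", "white", "black", "yellow", "dark", "light", "whole", "low",
    "high", "organic", "instant", "plain", "dry", "ripe", "wild", "young",
    "new", "special", "essential", "native", "multigrain", "soft", "hard",
    "fine", "coarse", "thick", "thin", "creamy", "crispy", "savoury",
    "savory", "spicy", "mild", "strong", "free", "skimmed", "semi",
    "chinese", "italian", "french", "greek", "indian", "spanish", "european",
    "continental", "african", "american", "durum", "lean", "fatty",
    "similar", "relevant", "common", "edible")
}

verb_base_lexicon <- function() {
  c("bake", "boil", "cook", "can", "smoke", "fry", "dry", "grill", "roast",
    "steam", "stew", "freeze", "mix", "fill", "slice", "dice", "grate",
    "pickle", "salt", "cure", "ferment", "mill", "grind", "toast", "mash",
    "chop", "mince", "marinate", "poach", "braise", "blanch", "squeeze",
    "press", "drain", "peel", "bottle", "flavor", "flavour", "prepare",
    "process", "concentrate", "dehydrate", "reconstitute", "sweeten",
    "skim", "tin", "glaze", "whip", "knead", "brew", "refine", "enrich",
    "fortify", "preserve", "smoke", "candy", "bread", "contain")
}

noun_ing_lexicon <- function() {
  c("pudding", "dressing", "dumpling", "herring", "icing", "stuffing",
    "seasoning", "filling", "topping", "shortening")
}

irregular_lemmas <- function() {
  c(leaves = "leaf", loaves = "loaf", halves = "half", knives = "knife",
    children = "child", mice = "mouse", geese = "goose", feet = "foot",
    teeth = "tooth", men = "man", women = "woman",
    frozen = "freeze", beaten = "beat", molten = "melt", ground = "grind",
    made = "make", baked = "bake", dried = "dry", fried = "fry")
}

#' Default filler-token stoplist for term-set extraction
#'
#' Tokens excluded from extracted noun/adjective/verb sets: abbreviation
#' fillers and list connectors that carry no food information.
#'
#' @return Character vector of lowercase tokens.
#' @export
term_stoplist <- function() {
  c("etc", "eg", "ie", "e", "g", "i", "similar", "and", "or")
}

## ---------------------------------------------------------------------------
## POS tagging

#' Rule-based part-of-speech tagging of a food name
#'
#' Assigns Penn-style tags to the word tokens of a (lowercased) food name.
#' Food names are noun phrases, so the default tag is noun; verbs are
#' recognized by -ed/-ing/-en morphology and a lexicon of cooking-process
#' bases, adjectives by a lexicon of common food qualifiers. Tagging runs on
#' the raw name (lowercased), not the punctuation-stripped form used for the
#' document-term matrix.
#'
#' @param name A single food name.
#' @return A data.frame with columns \code{token} and \code{tag} (one row per
#'   word token, in order). Tags used: NN/NNS (noun), JJ (adjective),
#'   VBD/VBG/VBN (verb), CC/IN/DT/PRP/FW/RB/SYM (non-content).
#' @examples
#' pos_tag_name("dried vine fruits (currants, raisins and sultanas)")
#' @export
pos_tag_name <- function(name) {
  tokens <- word_tokens(name)
  fw <- function_word_tags()
  adj <- adjective_lexicon()
  ning <- noun_ing_lexicon()
  irr <- irregular_lemmas()
  tag1 <- function(tok) {
    n <- nchar(tok)
    if (n == 1L) return("SYM")
    if (tok %in% names(fw)) return(fw[[tok]])
    if (tok %in% adj) return("JJ")
    if (!is.na(irr[tok]) && irr[[tok]] %in% verb_base_lexicon()) return("VBN")
    if (n >= 4L && ends_with(tok, "ed")) return("VBD")
    if (n >= 5L && ends_with(tok, "ing") && !(tok %in% ning)) return("VBG")
    if (n >= 4L && ends_with(tok, "ly")) return("RB")
    if (ends_with(tok, "s") && !ends_with(tok, "ss") &&
        !ends_with(tok, "us") && !ends_with(tok, "is")) return("NNS")
    "NN"
  }
  data.frame(token = tokens,
             tag = vapply(tokens, tag1, character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Lemmatization

#' Lemmatize a token given its part of speech
#'
#' Maps a token to its dictionary form: plural nouns are singularized,
#' inflected verbs (-ed, -ing, -en) are reduced to their base using a lexicon
#' of cooking-process verbs plus morphological heuristics. Unknown tokens are
#' returned unchanged.
#'
#' @param token A single lowercase token.
#' @param pos_tag Its Penn-style tag (e.g. "NNS", "VBD", "JJ"); anything
#'   starting with "N" is treated as a noun, "V" as a verb.
#' @return The lemma (character scalar).
#' @examples
#' lemmatize_token("dried", "VBD")   # "dry"
#' lemmatize_token("fruits", "NNS")  # "fruit"
#' @export
lemmatize_token <- function(token, pos_tag) {
  stopifnot(length(token) == 1L)
  tok <- tolower(token)
  irr <- irregular_lemmas()
  if (!is.na(irr[tok])) return(irr[[tok]])
  kind <- substr(pos_tag, 1L, 1L)
  if (kind == "N") return(lemmatize_noun(tok))
  if (kind == "V") return(lemmatize_verb(tok))
  tok
}

lemmatize_noun <- function(tok) {
  n <- nchar(tok)
  if (n >= 5L && ends_with(tok, "ies")) return(paste0(chop(tok, 3L), "y"))
  if (ends_with(tok, "oes")) return(chop(tok, 2L))
  for (suf in c("ses", "xes", "zes", "ches", "shes")) {
    if (ends_with(tok, suf)) return(chop(tok, 2L))
  }
  if (ends_with(tok, "s") && !ends_with(tok, "ss") &&
      !ends_with(tok, "us") && !ends_with(tok, "is") && n >= 3L) {
    return(chop(tok, 1L))
  }
  tok
}

lemmatize_verb <- function(tok) {
  verbs <- verb_base_lexicon()
  strip_infl <- function(base) {
    # candidates in preference order: bare strip, e-restore, undouble
    cands <- c(base, paste0(base, "e"))
    if (porter_double_c(base)) cands <- c(cands, chop(base, 1L))
    hit <- cands[cands %in% verbs]
    if (length(hit)) return(hit[[1L]])
    # heuristic fallback: undouble a doubled final consonant (not ll/ss)
    if (porter_double_c(base) &&
        !substr(base, nchar(base), nchar(base)) %in% c("l", "s")) {
      return(chop(base, 1L))
    }
    base
  }
  if (ends_with(tok, "ied") && nchar(tok) >= 4L) {
    return(paste0(chop(tok, 3L), "y"))
  }
  if (ends_with(tok, "ed") && nchar(tok) >= 4L) {
    return(strip_infl(chop(tok, 2L)))
  }
  if (ends_with(tok, "ing") && nchar(tok) >= 5L) {
    return(strip_infl(chop(tok, 3L)))
  }
  tok
}

## ---------------------------------------------------------------------------
## Term sets

#' Extract noun, adjective, and verb lemma sets from a food name
#'
#' POS-tags the (lowercased) name, groups content tokens into noun, adjective,
#' and verb sets, lemmatizes each member, removes stoplisted filler tokens,
#' and deduplicates. These sets drive the probabilistic description matcher.
#'
#' @param name A single food name (raw; lowercased internally).
#' @param tagger Tagging function with the contract of [pos_tag_name()]
#'   (injectable so tests can use deterministic stubs).
#' @param stoplist Filler tokens/lemmas to exclude; see [term_stoplist()].
#' @return An object of class \code{"term_sets"}: list with sorted character
#'   sets \code{nouns}, \code{adjectives}, \code{verbs}.
#' @examples
#' extract_term_sets("dried vine fruits (currants, raisins and sultanas)")
#' extract_term_sets("mushroom soup")
#' @export
extract_term_sets <- function(name, tagger = pos_tag_name,
                              stoplist = term_stoplist()) {
  tagged <- tagger(name)
  pick <- function(prefix) {
    rows <- tagged[startsWith(tagged$tag, prefix) &
                     !(tagged$token %in% stoplist), , drop = FALSE]
    if (!nrow(rows)) return(character(0))
    lemmas <- mapply(lemmatize_token, rows$token, rows$tag, USE.NAMES = FALSE)
    sort(unique(setdiff(lemmas, stoplist)))
  }
  structure(list(nouns = pick("N"),
                 adjectives = pick("J"),
                 verbs = pick("V")),
            class = "term_sets")
}

#' @export
print.term_sets <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = ", ") else "(empty)"
  cat("term sets\n")
  cat("  nouns:     ", fmt(x$nouns), "\n")
  cat("  adjectives:", fmt(x$adjectives), "\n")
  cat("  verbs:     ", fmt(x$verbs), "\n")
  invisible(x)
}

#' Part-of-speech counts and name length
#'
#' The four engineered classifier features of a name: number of nouns,
#' adjectives, and verbs found by tagging (stoplisted fillers excluded), and
#' the name length in word tokens. More nouns suggest a composite food;
#' adjectives and verbs suggest processing, hence a derivative or composite.
#'
#' @inheritParams extract_term_sets
#' @return Named integer vector
#'   \code{c(n_nouns, n_adjectives, n_verbs, name_length)}.
#' @examples
#' pos_length_features("mushroom soup")  # 2, 0, 0, 2
#' @export
pos_length_features <- function(name, tagger = pos_tag_name,
                                stoplist = term_stoplist()) {
  tagged <- tagger(name)
  content <- tagged[!(tagged$token %in% stoplist), , drop = FALSE]
  c(n_nouns = sum(startsWith(content$tag, "N")),
    n_adjectives = sum(startsWith(content$tag, "J")),
    n_verbs = sum(startsWith(content$tag, "V")),
    name_length = nrow(tagged))
}
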