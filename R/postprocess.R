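# Post-processing rules reconciling the classifier's food category with the
# category of the best vocabulary match from the description step.

#' Read a process lexicon from a plain-text file
#'
#' One lemma per line; blank lines and lines starting with '#' are ignored.
#' The lexicon lists processes that change the nature of a food (canning,
#' smoking, frying, baking, ...), used by the first post-processing rule.
#'
#' @param path Path to the lexicon file.
#' @return Character vector of lowercase lemmas.
#' @seealso [default_process_lexicon()]
#' @export
read_process_lexicon <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sort(unique(tolower(lines)))
}

#' The process lexicon shipped with the package
#'
#' Nature-changing process lemmas seeded from the FoodEx2 documentation's
#' examples plus common cooking processes. Users with the full official
#' process list can supply their own file via [read_process_lexicon()].
#'
#' @return Character vector of lowercase lemmas.
#' @export
default_process_lexicon <- function() {
  read_process_lexicon(system.file("extdata", "process_lexicon.txt",
                                   package = "foodcoder", mustWork = TRUE))
}

#' Apply the four post-processing rules to a predicted category
#'
#' Corrects the classifier's category using the name's own adjective/verb
#' lemmas and the category of the most relevant vocabulary match:
#' \enumerate{
#'   \item A name classified raw (r) whose adjective/verb lemmas contain a
#'     nature-changing process becomes a derivative (d).
#'   \item A name classified r or d whose best match is composite (s or c)
#'     takes the match's composite category.
#'   \item s with best match c becomes c.
#'   \item c with best match s becomes s.
#' }
#' At most one rule fires. When rules 1 and 2 both apply, the composite
#' evidence of rule 2 wins: a match to a composite food overrides the r-to-d
#' promotion. The result is idempotent for a fixed match category.
#'
#' @param name_sets \code{"term_sets"} of the query name (only the
#'   adjective/verb lemma sets are consulted, by rule 1).
#' @param predicted Classifier category, one of "r", "d", "s", "c".
#' @param match_category Category of the top description match, or NA/NULL
#'   when no match was found.
#' @param lexicon Process lemmas; see [default_process_lexicon()].
#' @return The corrected category (character scalar in \{r, d, s, c\}).
#' @examples
#' sets <- extract_term_sets("Cabbage Chinese boiled")
#' apply_category_rules(sets, "r", NA, default_process_lexicon())  # "d"
#' @export
apply_category_rules <- function(name_sets, predicted, match_category = NA,
                                 lexicon = default_process_lexicon()) {
  stopifnot(inherits(name_sets, "term_sets"))
  if (!is.character(predicted) || length(predicted) != 1L ||
      !(predicted %in% FOOD_CATEGORIES)) {
    stop("`predicted` must be one of ",
         paste(FOOD_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  match_cat <- if (is.null(match_category) || length(match_category) == 0L ||
                   is.na(match_category)) NA_character_ else match_category
  if (!is.na(match_cat) && !(match_cat %in% FOOD_CATEGORIES)) {
    stop("`match_category` must be one of ",
         paste(FOOD_CATEGORIES, collapse = ", "), " or NA", call. = FALSE)
  }
  adj_verb <- union(name_sets$adjectives, name_sets$verbs)

  # rule 2 (composite match dominates the r-to-d promotion of rule 1)
  if (predicted %in% c("r", "d") && !is.na(match_cat) &&
      match_cat %in% c("s", "c")) {
    return(match_cat)
  }
  # rule 1
  if (predicted == "r" && length(intersect(adj_verb, lexicon))) {
    return("d")
  }
  # rules 3 and 4
  if (predicted == "s" && !is.na(match_cat) && match_cat == "c") return("c")
  if (predicted == "c" && !is.na(match_cat) && match_cat == "s") return("s")
  predicted
}
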