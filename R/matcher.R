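# Probabilistic description matcher: rank coded-vocabulary entries against a
# query name by the probability of a similarity event combining noun overlap
# and pooled adjective/verb overlap of the POS-derived lemma sets.

#' Build a coded food vocabulary with cached term sets
#'
#' Wraps a data.frame of coded food records (columns \code{name},
#' \code{category} in \{r, d, s, c\}, \code{code}) and precomputes the
#' noun/adjective/verb lemma sets of every name once, so repeated queries do
#' not re-tag the vocabulary.
#'
#' @param records A data.frame with columns \code{name} (non-empty character),
#'   \code{category} (one of "r", "d", "s", "c"; raw commodity, derivative,
#'   simple composite, aggregated composite), and \code{code} (FoodEx2 code
#'   string). \code{category}/\code{code} may contain NA for uncoded entries.
#' @param tagger,stoplist Passed to [extract_term_sets()].
#' @return An object of class \code{"food_vocabulary"}.
#' @seealso [describe_food()], [simulate_food_vocabulary()]
#' @export
food_vocabulary <- function(records, tagger = pos_tag_name,
                            stoplist = term_stoplist()) {
  stopifnot(is.data.frame(records),
            all(c("name", "category", "code") %in% names(records)))
  if (!nrow(records)) stop("vocabulary must contain at least one record",
                           call. = FALSE)
  records$name <- as.character(records$name)
  records$category <- as.character(records$category)
  records$code <- as.character(records$code)
  if (any(!nzchar(records$name))) {
    stop("vocabulary names must be non-empty", call. = FALSE)
  }
  bad <- !is.na(records$category) & !(records$category %in% FOOD_CATEGORIES)
  if (any(bad)) {
    stop("invalid category value(s): ",
         paste(unique(records$category[bad]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(records$name, extract_term_sets,
                 tagger = tagger, stoplist = stoplist)
  structure(list(records = records, term_sets = sets),
            class = "food_vocabulary")
}

FOOD_CATEGORIES <- c("r", "d", "s", "c")

#' @export
print.food_vocabulary <- function(x, ...) {
  cat("<food vocabulary>", nrow(x$records), "coded records\n")
  tab <- table(factor(x$records$category, levels = FOOD_CATEGORIES))
  cat("  categories: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Retrieve candidate vocabulary entries sharing a noun with the query
#'
#' A vocabulary entry is a candidate iff its noun-lemma set intersects the
#' query's noun-lemma set. An empty query noun set retrieves nothing.
#'
#' @param query_sets A \code{"term_sets"} object for the query name.
#' @param vocabulary A [food_vocabulary()] object.
#' @return Integer vector of row indices into \code{vocabulary$records}.
#' @export
retrieve_candidates <- function(query_sets, vocabulary) {
  stopifnot(inherits(query_sets, "term_sets"),
            inherits(vocabulary, "food_vocabulary"))
  if (!length(query_sets$nouns)) return(integer(0))
  hits <- vapply(vocabulary$term_sets,
                 function(s) length(intersect(query_sets$nouns, s$nouns)) > 0L,
                 logical(1))
  which(hits)
}

#' Similarity between two food names' term sets
#'
#' The probability of the similarity event X = N (A + V): the product of the
#' Jaccard index of the noun-lemma sets and the Laplace-smoothed Jaccard
#' index of the pooled adjective-and-verb lemma sets,
#' \deqn{P(N) = |N_1 \cap N_2| / |N_1 \cup N_2|}
#' \deqn{P(A+V) = (|(A_1 \cup V_1) \cap (A_2 \cup V_2)| + 1) /
#'               (|(A_1 \cup V_1) \cup (A_2 \cup V_2)| + 2)}
#' Adjectives and verbs are pooled so that morphologically different forms
#' with the same meaning ("brown" JJ vs "browned" VBN) can still match; the
#' add-one smoothing keeps the weight positive when one name omits such
#' qualifiers. When both noun sets are empty P(N) is defined as 0 (no
#' topical evidence).
#'
#' @param query,candidate \code{"term_sets"} objects.
#' @return A list with \code{p_nouns}, \code{p_adj_verb}, and their product
#'   \code{weight}, all in [0, 1].
#' @examples
#' q <- extract_term_sets("dried vine fruits (currants, raisins and sultanas)")
#' d <- extract_term_sets("dried vine fruits (raisins etc.)")
#' term_set_similarity(q, d)  # weight 0.4
#' @export
term_set_similarity <- function(query, candidate) {
  stopifnot(inherits(query, "term_sets"), inherits(candidate, "term_sets"))
  n_int <- length(intersect(query$nouns, candidate$nouns))
  n_uni <- length(union(query$nouns, candidate$nouns))
  p_nouns <- if (n_uni == 0L) 0 else n_int / n_uni
  av1 <- union(query$adjectives, query$verbs)
  av2 <- union(candidate$adjectives, candidate$verbs)
  p_adj_verb <- (length(intersect(av1, av2)) + 1) /
    (length(union(av1, av2)) + 2)
  list(p_nouns = p_nouns, p_adj_verb = p_adj_verb,
       weight = p_nouns * p_adj_verb)
}

#' Describe a food name against a coded vocabulary
#'
#' Retrieves every vocabulary entry sharing at least one noun lemma with the
#' query, scores each with [term_set_similarity()], and returns the most
#' relevant match(es). Several entries can tie at the highest weight; all of
#' them are returned (sorted by name) and the user chooses. An empty result
#' signals that the food is not represented in the vocabulary.
#'
#' @param query_name The food name to describe.
#' @param vocabulary A [food_vocabulary()] object.
#' @param all_candidates If TRUE, return every scored candidate (sorted by
#'   decreasing weight, then name) instead of only the top-weight ties.
#' @inheritParams food_vocabulary
#' @return A data.frame with columns \code{query}, \code{matched_name},
#'   \code{code}, \code{category}, \code{p_nouns}, \code{p_adj_verb},
#'   \code{weight}; zero rows when no candidate shares a noun.
#' @examples
#' vocab <- food_vocabulary(data.frame(
#'   name = c("field mushroom", "canned mushroom", "mushroom soup",
#'            "fruit soup", "apple juice", "raw carrot"),
#'   category = c("r", "d", "c", "c", "d", "r"),
#'   code = c("A0001", "A0002", "A041R", "A0004", "A0005", "A0006")))
#' describe_food("mushroom soup", vocab)
#' @export
describe_food <- function(query_name, vocabulary, all_candidates = FALSE,
                          tagger = pos_tag_name, stoplist = term_stoplist()) {
  stopifnot(inherits(vocabulary, "food_vocabulary"))
  qs <- extract_term_sets(query_name, tagger = tagger, stoplist = stoplist)
  idx <- retrieve_candidates(qs, vocabulary)
  empty <- data.frame(query = character(0), matched_name = character(0),
                      code = character(0), category = character(0),
                      p_nouns = numeric(0), p_adj_verb = numeric(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  scores <- lapply(vocabulary$term_sets[idx],
                   function(s) term_set_similarity(qs, s))
  out <- data.frame(
    query = query_name,
    matched_name = vocabulary$records$name[idx],
    code = vocabulary$records$code[idx],
    category = vocabulary$records$category[idx],
    p_nouns = vapply(scores, `[[`, numeric(1), "p_nouns"),
    p_adj_verb = vapply(scores, `[[`, numeric(1), "p_adj_verb"),
    weight = vapply(scores, `[[`, numeric(1), "weight"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$matched_name), , drop = FALSE]
  if (!all_candidates) {
    out <- out[out$weight == max(out$weight), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
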