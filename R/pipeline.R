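#' Standardize food names: classify, describe, and post-process
#'
#' Runs the full pipeline on a vector of food names: the ensemble predicts a
#' food-chain category, the matcher retrieves the most relevant coded
#' vocabulary entry, and the post-processing rules reconcile the two. When
#' several vocabulary entries tie at the top weight the lexicographically
#' first is used for post-processing (and \code{n_matches} flags the tie so
#' the user can inspect the alternatives with [describe_food()]).
#'
#' @param names Character vector of food names to standardize.
#' @param ensemble A fitted [food_ensemble()].
#' @param vocabulary A [food_vocabulary()].
#' @param lexicon Process lemmas for rule 1; see [default_process_lexicon()].
#' @inheritParams food_vocabulary
#' @return Data.frame with one row per name: \code{name},
#'   \code{predicted_category} (classifier output), \code{matched_name},
#'   \code{code}, \code{match_category}, \code{weight} (NA when nothing was
#'   retrieved), \code{n_matches} (ties at top weight), and
#'   \code{final_category} (after the rules).
#' @examples
#' \donttest{
#' vocab_df <- simulate_food_vocabulary(n_r = 40, n_d = 30, n_s = 15,
#'                                      n_c = 15, seed = 7)
#' fit <- food_ensemble(vocab_df, seed = 7)
#' vocab <- food_vocabulary(vocab_df)
#' standardize_foods(c("mushroom soup", "apple juice"), fit, vocab)
#' }
#' @export
standardize_foods <- function(names, ensemble, vocabulary,
                              lexicon = default_process_lexicon(),
                              tagger = pos_tag_name,
                              stoplist = term_stoplist()) {
  stopifnot(inherits(ensemble, "food_ensemble"),
            inherits(vocabulary, "food_vocabulary"))
  names <- as.character(names)
  predicted <- predict(ensemble, names)
  rows <- lapply(seq_along(names), function(i) {
    matches <- describe_food(names[i], vocabulary,
                             tagger = tagger, stoplist = stoplist)
    sets <- extract_term_sets(names[i], tagger = tagger, stoplist = stoplist)
    if (nrow(matches)) {
      top <- matches[1L, ]
      final <- apply_category_rules(sets, predicted[i], top$category,
                                    lexicon)
      data.frame(name = names[i], predicted_category = predicted[i],
                 matched_name = top$matched_name, code = top$code,
                 match_category = top$category, weight = top$weight,
                 n_matches = nrow(matches), final_category = final,
                 stringsAsFactors = FALSE)
    } else {
      final <- apply_category_rules(sets, predicted[i], NA, lexicon)
      data.frame(name = names[i], predicted_category = predicted[i],
                 matched_name = NA_character_, code = NA_character_,
                 match_category = NA_character_, weight = NA_real_,
                 n_matches = 0L, final_category = final,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
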