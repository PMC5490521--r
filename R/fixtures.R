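# Seeded generator of synthetic coded food vocabularies. Real FoodEx2
# extracts are licensed, so tests and examples run on generated vocabularies
# with the same structure: names whose wording signals the food-chain
# category, plus grammar-valid synthetic codes. These are synthetic
# stand-ins, not FoodEx2 content.

fixture_pools <- function() {
  list(
    commodities = c("barley", "wheat", "oat", "rye", "rice", "maize",
                    "millet", "buckwheat", "apple", "pear", "cherry", "plum",
                    "peach", "apricot", "grape", "orange", "lemon", "carrot",
                    "cabbage", "spinach", "potato", "tomato", "onion",
                    "garlic", "pea", "bean", "lentil", "almond", "walnut",
                    "hazelnut", "salmon", "trout", "beef", "pork", "chicken",
                    "lamb", "mushroom", "pumpkin", "cucumber", "beetroot"),
    raw_forms = c("grains", "fresh", "raw", "seeds", "leaves", "whole",
                  "root", "fruits"),
    process_products = c("flour", "flakes", "oil", "juice", "powder",
                         "syrup", "dried", "canned", "smoked", "pickled",
                         "boiled", "roasted"),
    simple_templates = c("%s compote", "%s jam", "%s marmalade", "%s puree",
                         "%s spread", "muesli with %s", "%s porridge"),
    aggregated_templates = c("%s soup", "%s salad", "%s pie", "%s casserole",
                             "%s and vegetables meal", "%s risotto",
                             "pizza with %s")
  )
}

random_code_chars <- function(n) {
  paste(sample(c(0:9, LETTERS), n, replace = TRUE), collapse = "")
}

random_foodex2_code <- function() {
  base <- paste0("A", random_code_chars(4L))
  n_facets <- sample(0:2, 1L, prob = c(0.7, 0.2, 0.1))
  if (n_facets == 0L) return(base)
  facets <- replicate(n_facets, {
    paste0("F", sprintf("%02d", sample(1:32, 1L)), ".A", random_code_chars(4L))
  })
  paste0(base, "#", paste(facets, collapse = "$"))
}

#' Generate a synthetic coded food vocabulary
#'
#' Produces a labeled vocabulary that emulates the structure of a FoodEx2
#' category extract: raw-commodity names are bare commodity nouns with a
#' raw-form word ("barley grains"), derivatives add a process product or
#' process participle ("buckwheat flour", "carrot dried"), simple composites
#' follow two-ingredient product templates ("apple compote"), and aggregated
#' composites follow dish templates ("mushroom soup"). Every record carries a
#' synthetic, grammar-valid FoodEx2-style code (parsable by
#' [parse_foodex2()]; the codes are invented, not official terms). The
#' default sizes give a 400-record corpus with the skewed category mix
#' observed in real category extracts (47/33/14/6\% for r/d/s/c).
#'
#' The wording pools make the corpus nearly separable by term features,
#' which is what a category extract looks like at small scale; \code{noise}
#' injects random commodity words to blur the signal for stress tests.
#'
#' @param n_r,n_d,n_s,n_c Records per category.
#' @param seed Integer; the vocabulary is a pure function of the arguments.
#' @param noise Fraction in [0, 1] of records that get a random extra
#'   commodity word appended (default 0).
#' @return Data.frame with columns \code{name}, \code{category}, \code{code}.
#' @examples
#' head(simulate_food_vocabulary(n_r = 4, n_d = 3, n_s = 2, n_c = 1, seed = 1))
#' @export
simulate_food_vocabulary <- function(n_r = 188L, n_d = 132L, n_s = 56L,
                                     n_c = 24L, seed = 1L, noise = 0) {
  stopifnot(n_r >= 0, n_d >= 0, n_s >= 0, n_c >= 0,
            noise >= 0, noise <= 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  pools <- fixture_pools()

  draw_names <- function(n, builder, combos) {
    if (n == 0L) return(character(0))
    picked <- combos[sample(nrow(combos), n, replace = n > nrow(combos)), ,
                     drop = FALSE]
    vapply(seq_len(nrow(picked)),
           function(i) builder(picked[i, 1L], picked[i, 2L]), character(1))
  }
  grid2 <- function(a, b) expand.grid(a = a, b = b,
                                      stringsAsFactors = FALSE)

  r_names <- draw_names(n_r, function(a, b) paste(a, b),
                        grid2(pools$commodities, pools$raw_forms))
  d_names <- draw_names(n_d, function(a, b) paste(a, b),
                        grid2(pools$commodities, pools$process_products))
  s_names <- draw_names(n_s, function(a, b) sprintf(b, a),
                        grid2(pools$commodities, pools$simple_templates))
  c_names <- draw_names(n_c, function(a, b) sprintf(b, a),
                        grid2(pools$commodities, pools$aggregated_templates))

  out <- data.frame(
    name = c(r_names, d_names, s_names, c_names),
    category = rep(c("r", "d", "s", "c"), c(n_r, n_d, n_s, n_c)),
    stringsAsFactors = FALSE)
  if (noise > 0 && nrow(out)) {
    hit <- runif(nrow(out)) < noise
    extra <- sample(pools$commodities, sum(hit), replace = TRUE)
    out$name[hit] <- paste(out$name[hit], extra)
  }
  out$code <- vapply(seq_len(nrow(out)),
                     function(i) random_foodex2_code(), character(1))
  out
}

#' Bundled reference examples for the matcher and the post-processing rules
#'
#' Small, hand-checkable cases used throughout the tests and documentation:
#' two description walkthroughs with their expected lemma sets, candidate
#' neighborhoods, and similarity weights (0.4 and 0.5), and seven
#' category-correction cases with the classifier category, the category of
#' the best vocabulary match, and the expected corrected category.
#'
#' @return A list with elements \code{matching} (list of two cases, each a
#'   list with \code{query}, \code{expected_match}, \code{other_candidates},
#'   \code{p_nouns}, \code{p_adj_verb}, \code{weight}, \code{query_sets})
#'   and \code{postprocessing} (data.frame with columns \code{name},
#'   \code{predicted}, \code{match_category}, \code{expected}).
#' @export
reference_examples <- function() {
  list(
    matching = list(
      list(
        query = "dried vine fruits (currants, raisins and sultanas)",
        expected_match = "dried vine fruits (raisins etc.)",
        other_candidates = c("fruit soup dry", "African oil palm fruits",
                             "native currant", "Malaga raisins flavor",
                             "juice red currant", "sultanas flavor"),
        query_sets = list(nouns = c("currant", "fruit", "raisin",
                                    "sultana", "vine"),
                          adjectives = character(0), verbs = "dry"),
        p_nouns = 3 / 5, p_adj_verb = 2 / 3, weight = 0.4),
      list(
        query = "mushroom soup",
        expected_match = "mushroom soup",
        other_candidates = c("field mushroom", "canned mushroom",
                             "mushroom flavor", "mushroom salad",
                             "pizza and similar with cheese and mushrooms",
                             "honey mushrooms"),
        query_sets = list(nouns = c("mushroom", "soup"),
                          adjectives = character(0), verbs = character(0)),
        p_nouns = 1, p_adj_verb = 1 / 2, weight = 0.5)
    ),
    postprocessing = data.frame(
      name = c("Cabbage Chinese boiled", "Marzipan", "Gingerbread",
               "Water, bottled, flavored, citrus",
               "Salad, tuna-vegetable, canned", "Multigrain rolls",
               "Croissant, filled with jam"),
      predicted = c("r", "r", "r", "d", "d", "c", "s"),
      match_category = c(NA, "s", "c", "s", "c", "s", "c"),
      expected = c("d", "s", "c", "s", "c", "s", "c"),
      stringsAsFactors = FALSE)
  )
}
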