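# Shared helpers: small vocabularies and independent brute-force oracles.

toy_mushroom_vocab <- function() {
  food_vocabulary(data.frame(
    name = c("field mushroom", "canned mushroom", "mushroom soup",
             "fruit soup", "apple juice", "raw carrot"),
    category = c("r", "d", "c", "c", "d", "r"),
    code = c("A0001", "A0002", "A041R", "A0004", "A0005", "A0006"),
    stringsAsFactors = FALSE))
}

# brute-force retrieval: scan every entry for a shared noun lemma
brute_force_retrieve <- function(query_sets, vocabulary) {
  which(vapply(vocabulary$term_sets, function(s) {
    length(intersect(query_sets$nouns, s$nouns)) > 0L
  }, logical(1)))
}

# brute-force top weight: score *every* vocabulary entry from first
# principles (set arithmetic written out, no call to term_set_similarity)
brute_force_top <- function(query_name, vocabulary) {
  qs <- extract_term_sets(query_name)
  weights <- vapply(vocabulary$term_sets, function(s) {
    nu <- length(union(qs$nouns, s$nouns))
    pn <- if (nu == 0L) 0 else length(intersect(qs$nouns, s$nouns)) / nu
    av1 <- union(qs$adjectives, qs$verbs)
    av2 <- union(s$adjectives, s$verbs)
    pav <- (length(intersect(av1, av2)) + 1) / (length(union(av1, av2)) + 2)
    pn * pav
  }, numeric(1))
  top <- max(weights)
  list(weights = weights, top = top,
       names = sort(vocabulary$records$name[weights == top & weights > 0]))
}

# random grammar-valid code strings in either input dialect
random_code_string <- function(canonical = TRUE) {
  chars <- function(n) paste(sample(c(0:9, LETTERS), n, replace = TRUE),
                             collapse = "")
  base <- paste0("A", chars(4))
  n_facets <- sample(0:3, 1)
  if (n_facets == 0) return(base)
  facets <- replicate(n_facets,
                      paste0("F", sample(1:32, 1), ".A", chars(4)))
  sep <- if (canonical) "#" else "$"
  paste0(base, sep, paste(facets, collapse = "$"))
}
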