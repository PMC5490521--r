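test_that("retrieval returns exactly the entries sharing a noun lemma", {
  vocab <- toy_mushroom_vocab()
  qs <- extract_term_sets("mushroom soup")
  idx <- retrieve_candidates(qs, vocab)
  expect_setequal(vocab$records$name[idx],
                  c("field mushroom", "canned mushroom", "mushroom soup",
                    "fruit soup"))
  # empty query noun set retrieves nothing
  empty <- structure(list(nouns = character(0), adjectives = "fresh",
                          verbs = character(0)), class = "term_sets")
  expect_identical(retrieve_candidates(empty, vocab), integer(0))
})

test_that("retrieval agrees with a brute-force scan on random fixtures", {
  set.seed(3)
  for (i in 1:10) {
    vocab_df <- simulate_food_vocabulary(n_r = 10, n_d = 8, n_s = 6,
                                         n_c = 6, seed = 100 + i)
    vocab <- food_vocabulary(vocab_df)
    queries <- sample(vocab_df$name, 5)
    for (q in queries) {
      qs <- extract_term_sets(q)
      expect_identical(retrieve_candidates(qs, vocab),
                       brute_force_retrieve(qs, vocab))
    }
  }
})

test_that("similarity reproduces the two description walkthroughs", {
  q <- extract_term_sets("dried vine fruits (currants, raisins and sultanas)")
  cand <- extract_term_sets("dried vine fruits (raisins etc.)")
  sim <- term_set_similarity(q, cand)
  expect_identical(sim$p_nouns, 3 / 5)
  expect_identical(sim$p_adj_verb, 2 / 3)
  expect_identical(sim$weight, (3 / 5) * (2 / 3))
  expect_equal(sim$weight, 0.4)

  q2 <- extract_term_sets("mushroom soup")
  sim2 <- term_set_similarity(q2, extract_term_sets("mushroom soup"))
  expect_identical(sim2$p_nouns, 1)
  expect_identical(sim2$p_adj_verb, 0.5)
  expect_identical(sim2$weight, 0.5)
})

test_that("similarity edge cases: disjoint nouns, empty sets, self-match", {
  a <- extract_term_sets("apple juice")
  b <- extract_term_sets("mushroom soup")
  expect_equal(term_set_similarity(a, b)$weight, 0)
  # both noun sets empty: defined as zero topical evidence
  e <- extract_term_sets("")
  expect_equal(term_set_similarity(e, e)$p_nouns, 0)
  # identical sets with u adjective/verb lemmas score (u+1)/(u+2) < 1
  s <- extract_term_sets("dried smoked salmon")
  u <- length(union(s$adjectives, s$verbs))
  expect_gte(u, 1)
  self <- term_set_similarity(s, s)
  expect_equal(self$weight, (u + 1) / (u + 2))
  expect_lt(self$weight, 1)
})

test_that("similarity is symmetric and bounded on random pairs", {
  set.seed(5)
  vocab_df <- simulate_food_vocabulary(n_r = 12, n_d = 12, n_s = 8, n_c = 8,
                                       seed = 55)
  sets <- lapply(vocab_df$name, extract_term_sets)
  for (i in 1:40) {
    ab <- sample(length(sets), 2)
    s1 <- term_set_similarity(sets[[ab[1]]], sets[[ab[2]]])
    s2 <- term_set_similarity(sets[[ab[2]]], sets[[ab[1]]])
    expect_identical(s1, s2)
    expect_gte(s1$weight, 0)
    expect_lte(s1$weight, 1)
    u <- length(union(union(sets[[ab[1]]]$adjectives, sets[[ab[1]]]$verbs),
                      union(sets[[ab[2]]]$adjectives, sets[[ab[2]]]$verbs)))
    expect_gte(s1$p_adj_verb, 1 / (u + 2))
    expect_lte(s1$p_adj_verb, (u + 1) / (u + 2))
    # weight is zero exactly when the noun sets are disjoint
    disjoint <- length(intersect(sets[[ab[1]]]$nouns,
                                 sets[[ab[2]]]$nouns)) == 0L
    expect_identical(s1$weight == 0, disjoint)
  }
})

test_that("describe returns the top-weight match with its code", {
  vocab <- toy_mushroom_vocab()
  res <- describe_food("mushroom soup", vocab)
  expect_equal(nrow(res), 1L)
  expect_equal(res$matched_name, "mushroom soup")
  expect_equal(res$code, "A041R")
  expect_equal(res$weight, 0.5)
  # query sharing no noun with any entry
  expect_equal(nrow(describe_food("rye bread", vocab)), 0L)
})

test_that("describe returns all ties at the top weight, sorted by name", {
  vocab <- food_vocabulary(data.frame(
    name = c("sour cherries", "cherries sweet", "nanking cherries",
             "cornelian cherries", "black cherries", "apple juice"),
    category = c("r", "r", "r", "r", "r", "d"),
    code = c("A01GH", "A01GK", "A0DVN", "A0DVP", "A0DVR", "A0005"),
    stringsAsFactors = FALSE))
  # "sour cherries", "cherries sweet", "black cherries" all score
  # 1 * (0+1)/(2+2) against the query's adjective "fresh"; so does
  # "nanking cherries", whose -ing token the tagger reads as a verb
  res <- describe_food("cherry, fresh", vocab)
  expect_equal(nrow(res), 4L)
  expect_length(unique(res$weight), 1L)
  expect_identical(res$matched_name, sort(res$matched_name))
  expect_setequal(res$matched_name,
                  c("sour cherries", "cherries sweet", "black cherries",
                    "nanking cherries"))
})

test_that("describe's top weight equals a brute-force scan on random fixtures", {
  set.seed(9)
  for (i in 1:10) {
    vocab_df <- simulate_food_vocabulary(n_r = 10, n_d = 8, n_s = 6, n_c = 6,
                                         seed = 200 + i)
    vocab <- food_vocabulary(vocab_df)
    for (q in sample(vocab_df$name, 4)) {
      oracle <- brute_force_top(q, vocab)
      res <- describe_food(q, vocab)
      expect_equal(res$weight[1], oracle$top)
      expect_identical(res$matched_name, oracle$names)
    }
  }
})
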