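test_that("document-term matrix counts stems and applies the sparsity cut", {
  # 100 names: "flour" in 5 docs, "quince" in 1; boundary is strict (> 1%)
  names_vec <- c(paste("wheat flour", 1:5), "quince fresh",
                 paste("apple pie", 1:94))
  feats <- build_feature_matrix(data.frame(name = names_vec),
                                sparsity_threshold = 0.01)
  expect_true("flour" %in% feats$vocabulary)
  expect_false("quinc" %in% feats$vocabulary)   # 1/100 is not > 1%
  expect_true(all(c("appl", "pie", "wheat") %in% feats$vocabulary))
  expect_equal(ncol(feats$matrix), length(feats$vocabulary) + 4L)

  # the walkthrough record contributes count 1 under each of its stems
  feats2 <- build_feature_matrix(
    data.frame(name = c("dried vine fruits (raisins etc.)",
                        "mushroom soup", "mushroom soup fresh")),
    sparsity_threshold = 0.01)
  row1 <- feats2$matrix[1, ]
  for (stem in c("dri", "vine", "fruit", "raisin", "etc")) {
    expect_equal(unname(row1[paste0("term_", stem)]), 1)
  }
  expect_equal(unname(row1["term_mushroom"]), 0)
})

test_that("term counts agree with an independent brute-force recount", {
  vocab_df <- simulate_food_vocabulary(n_r = 20, n_d = 15, n_s = 10,
                                       n_c = 10, seed = 21)
  feats <- build_feature_matrix(vocab_df, sparsity_threshold = 0.01)
  for (i in seq_len(nrow(vocab_df))) {
    stems <- porter_stem(tokenize_name(preprocess_name(vocab_df$name[i])))
    recount <- vapply(feats$vocabulary,
                      function(term) sum(stems == term), numeric(1))
    expect_equal(unname(feats$matrix[i, seq_along(feats$vocabulary)]),
                 unname(recount))
  }
  expect_error(build_feature_matrix(data.frame(name = character(0))),
               "empty corpus")
})

test_that("feature matrix is order-independent up to row permutation", {
  vocab_df <- simulate_food_vocabulary(n_r = 15, n_d = 10, n_s = 8, n_c = 7,
                                       seed = 31)
  perm <- rev(seq_len(nrow(vocab_df)))
  f1 <- build_feature_matrix(vocab_df)
  f2 <- build_feature_matrix(vocab_df[perm, ])
  expect_identical(f1$vocabulary, f2$vocabulary)
  expect_equal(f1$matrix, f2$matrix[order(perm), ])
})

test_that("majority vote: plurality, unanimity, and priority tie-breaks", {
  ballot <- function(svm, rf, boosting, maxent) {
    matrix(c(svm, rf, boosting, maxent), nrow = 1,
           dimnames = list(NULL, c("svm", "rf", "boosting", "maxent")))
  }
  expect_equal(majority_vote(ballot("r", "r", "d", "s")), "r")
  expect_equal(majority_vote(ballot("c", "c", "c", "c")), "c")
  # 2-2 tie: maxent outranks everything
  expect_equal(majority_vote(ballot("r", "r", "d", "d")), "d")
  # 2-2 tie where maxent is not among the leaders cannot occur in a 2-2
  # split of four voters; 1-1-1-1 tie: maxent wins outright
  expect_equal(majority_vote(ballot("r", "d", "s", "c")), "c")
  # tie between rf and svm camps, maxent in the rf camp
  expect_equal(majority_vote(ballot("s", "r", "s", "r")), "r")
})

test_that("identical ballots collapse the ensemble to a single member", {
  set.seed(13)
  for (i in 1:20) {
    lab <- sample(c("r", "d", "s", "c"), 1)
    b <- matrix(lab, nrow = 1, ncol = 4,
                dimnames = list(NULL, c("svm", "rf", "boosting", "maxent")))
    expect_equal(majority_vote(b), lab)
  }
})

test_that("evaluation metrics follow the precision/recall/accuracy formulas", {
  # TP=3, FP=1, FN=1, TN=5 for category r
  predicted <- c(rep("r", 4), rep("d", 6))
  reference <- c(rep("r", 3), "d", "r", rep("d", 5))
  ev <- evaluate_classifier(predicted, reference)
  r_row <- ev$per_category[ev$per_category$category == "r", ]
  expect_equal(r_row[, c("tp", "fp", "fn", "tn")],
               data.frame(tp = 3L, fp = 1L, fn = 1L, tn = 5L),
               ignore_attr = TRUE)
  expect_equal(r_row$precision, 0.75)
  expect_equal(r_row$recall, 0.75)
  expect_equal(r_row$accuracy, 0.8)

  perfect <- evaluate_classifier(reference, reference)
  expect_true(all(perfect$per_category$precision == 1))
  expect_true(all(perfect$per_category$recall == 1))
  expect_equal(perfect$overall_accuracy, 1)

  # a category never predicted has undefined precision, not zero
  ev2 <- evaluate_classifier(c("r", "r"), c("r", "d"))
  d_row <- ev2$per_category[ev2$per_category$category == "d", ]
  expect_true(is.na(d_row$precision))
  expect_equal(d_row$recall, 0)
})

test_that("metrics match a hand-tallied confusion matrix on 20 records", {
  predicted <- c("r", "r", "d", "d", "r", "s", "c", "d", "r", "s",
                 "c", "c", "d", "r", "s", "r", "d", "c", "s", "r")
  reference <- c("r", "d", "d", "d", "r", "s", "s", "d", "r", "c",
                 "c", "c", "r", "r", "s", "r", "d", "c", "s", "d")
  ev <- evaluate_classifier(predicted, reference)
  # hand tally: r predicted 7 (5 correct), truth r = 6
  r_row <- ev$per_category[ev$per_category$category == "r", ]
  expect_equal(r_row$tp, 5L); expect_equal(r_row$fp, 2L)
  expect_equal(r_row$fn, 1L); expect_equal(r_row$tn, 12L)
  expect_equal(r_row$precision, 5 / 7)
  expect_equal(r_row$recall, 5 / 6)
  s_row <- ev$per_category[ev$per_category$category == "s", ]
  expect_equal(s_row$tp, 3L); expect_equal(s_row$fp, 1L)
  expect_equal(s_row$fn, 1L)
  expect_equal(ev$overall_accuracy, 15 / 20)
})

test_that("cross-validation partitions records exactly once per fold", {
  toy <- data.frame(
    name = c("barley grains", "wheat fresh", "oat raw", "rye seeds",
             "apple fresh", "apple juice", "wheat flour", "oat flakes",
             "carrot dried", "pear juice"),
    category = rep(c("r", "d"), each = 5), stringsAsFactors = FALSE)
  cv <- cross_validate(toy, k = nrow(toy), seed = 4)  # leave-one-out
  expect_equal(sort(cv$fold), 1:10)
  expect_equal(length(cv$predicted), 10L)
  expect_true(all(cv$predicted %in% c("r", "d", "s", "c")))
  expect_error(cross_validate(toy, k = 11), "cannot exceed")
  expect_error(cross_validate(toy, k = 1), "at least 2")
})

test_that("ensemble training is seeded, deterministic, and near-separable", {
  vocab_df <- simulate_food_vocabulary(n_r = 47, n_d = 33, n_s = 14,
                                       n_c = 16, seed = 7)
  fit <- food_ensemble(vocab_df, seed = 7)
  expect_s3_class(fit, "food_ensemble")
  train_acc <- mean(predict(fit, vocab_df) == vocab_df$category)
  expect_gte(train_acc, 0.95)

  probe <- c("mushroom soup", "apple juice", "barley grains",
             "wheat flour", "cherry jam", "pizza with beef")
  fit2 <- food_ensemble(vocab_df, seed = 7)
  expect_identical(predict(fit, probe), predict(fit2, probe))
  expect_true(all(predict(fit, probe) %in% c("r", "d", "s", "c")))

  # permuting training rows (with labels) leaves predictions unchanged
  perm <- sample(nrow(vocab_df))
  fit3 <- food_ensemble(vocab_df[perm, ], seed = 7)
  expect_identical(predict(fit3, probe), predict(fit, probe))
  expect_identical(predict(fit3, vocab_df$name), predict(fit, vocab_df$name))

  expect_error(food_ensemble(data.frame(name = c("a b", "c d"),
                                        category = c("r", "r"))),
               "two categories")
})
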