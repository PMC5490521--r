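# Four-model majority-vote ensemble over a stemmed document-term matrix:
# support vector machine (e1071), random forest (randomForest), gradient
# boosting (xgboost), and maximum entropy realized as multinomial logistic
# regression (nnet::multinom).

ENSEMBLE_MEMBERS <- c("svm", "rf", "boosting", "maxent")
# tie-break priority: descending single-model cross-validated accuracy
VOTE_PRIORITY <- c("maxent", "rf", "svm", "boosting")

#' Build the document-term feature matrix
#'
#' Each food name is preprocessed, tokenized, and Porter-stemmed; the matrix
#' counts the retained stems per name. A stem is retained iff its document
#' frequency strictly exceeds \code{sparsity_threshold} of the corpus (terms
#' appearing in at most that fraction of names are removed). Four engineered
#' columns are appended: the number of nouns, adjectives, and verbs found by
#' POS tagging, and the name length in tokens.
#'
#' @param records Data.frame with a \code{name} column, or a character vector
#'   of names.
#' @param sparsity_threshold Fraction in (0, 1); default 0.01 removes terms
#'   present in at most 1\% of names.
#' @param tagger Tagging function for the engineered features; see
#'   [pos_tag_name()].
#' @return A list of class \code{"food_features"}: \code{matrix} (numeric,
#'   one row per record, \code{|vocabulary| + 4} columns), \code{vocabulary}
#'   (the retained stems, sorted), \code{sparsity_threshold}.
#' @export
build_feature_matrix <- function(records, sparsity_threshold = 0.01,
                                 tagger = pos_tag_name) {
  names_vec <- if (is.data.frame(records)) as.character(records$name)
               else as.character(records)
  if (!length(names_vec)) stop("empty corpus", call. = FALSE)
  stopifnot(sparsity_threshold > 0, sparsity_threshold < 1)
  stem_lists <- lapply(names_vec, function(nm) {
    porter_stem(tokenize_name(preprocess_name(nm)))
  })
  n <- length(names_vec)
  doc_freq <- table(unlist(lapply(stem_lists, unique)))
  vocabulary <- sort(names(doc_freq)[doc_freq > sparsity_threshold * n])
  mat <- featurize_names(names_vec, vocabulary, stem_lists, tagger)
  structure(list(matrix = mat, vocabulary = vocabulary,
                 sparsity_threshold = sparsity_threshold),
            class = "food_features")
}

# count matrix over a fixed stem vocabulary + the 4 engineered features
featurize_names <- function(names_vec, vocabulary, stem_lists = NULL,
                            tagger = pos_tag_name) {
  if (is.null(stem_lists)) {
    stem_lists <- lapply(names_vec, function(nm) {
      porter_stem(tokenize_name(preprocess_name(nm)))
    })
  }
  term_cols <- if (length(vocabulary)) {
    t(vapply(stem_lists,
             function(st) {
               tab <- table(factor(st, levels = vocabulary))
               as.numeric(tab)
             },
             numeric(length(vocabulary))))
  } else {
    matrix(0, nrow = length(names_vec), ncol = 0L)
  }
  if (length(vocabulary) == 1L) term_cols <- matrix(term_cols, ncol = 1L)
  pos <- t(vapply(names_vec, pos_length_features, numeric(4L),
                  tagger = tagger))
  mat <- cbind(term_cols, pos)
  colnames(mat) <- c(term_feature_names(vocabulary),
                     c("n_nouns", "n_adjectives", "n_verbs", "name_length"))
  rownames(mat) <- NULL
  mat
}

term_feature_names <- function(vocabulary) {
  if (!length(vocabulary)) return(character(0))
  make.unique(paste0("term_", make.names(vocabulary)))
}

#' Fit the four-member majority-vote food-category ensemble
#'
#' Trains a support vector machine, a random forest, a gradient-boosted tree
#' model, and a maximum-entropy (multinomial logistic) model on the
#' document-term feature matrix of the coded records, to predict the
#' food-chain category r (raw commodity), d (derivative), s (simple
#' composite), or c (aggregated composite) from a food name. All stochastic
#' components (random forest, boosting) are driven by \code{seed}, so a fit
#' is reproducible.
#'
#' @param data Data.frame with columns \code{name} and \code{category}
#'   (values in \{r, d, s, c\}), e.g. from [simulate_food_vocabulary()].
#' @param sparsity_threshold Passed to [build_feature_matrix()].
#' @param seed Integer seed fixing all stochastic components.
#' @param tagger POS tagger used for the engineered features.
#' @return An object of class \code{"food_ensemble"} with
#'   print/summary/predict methods.
#' @examples
#' \donttest{
#' vocab <- simulate_food_vocabulary(n_r = 40, n_d = 30, n_s = 15, n_c = 15,
#'                                   seed = 7)
#' fit <- food_ensemble(vocab, seed = 7)
#' predict(fit, c("barley grains", "mushroom soup"))
#' }
#' @export
food_ensemble <- function(data, sparsity_threshold = 0.01, seed = 1L,
                          tagger = pos_tag_name) {
  stopifnot(is.data.frame(data), all(c("name", "category") %in% names(data)))
  y_chr <- as.character(data$category)
  if (!all(y_chr %in% FOOD_CATEGORIES)) {
    stop("categories must be in {r, d, s, c}", call. = FALSE)
  }
  if (length(unique(y_chr)) < 2L) {
    stop("training data must contain at least two categories", call. = FALSE)
  }
  feats <- build_feature_matrix(data, sparsity_threshold, tagger)
  y <- factor(y_chr, levels = intersect(FOOD_CATEGORIES, unique(y_chr)))
  x <- feats$matrix

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  models <- list(
    svm = e1071::svm(x, y, kernel = "linear", scale = FALSE),
    rf = {
      set.seed(seed + 1L)
      randomForest::randomForest(x, y, ntree = 500L)
    },
    boosting = xgboost::xgboost(x, y, nrounds = 60L, max_depth = 4L,
                                nthreads = 1L, seed = seed + 2L,
                                verbosity = 0L),
    maxent = fit_maxent(x, y)
  )
  structure(list(models = models,
                 vocabulary = feats$vocabulary,
                 sparsity_threshold = sparsity_threshold,
                 levels = levels(y),
                 seed = seed,
                 tagger = tagger,
                 n_train = nrow(x)),
            class = "food_ensemble")
}

fit_maxent <- function(x, y) {
  df <- data.frame(x, check.names = FALSE)
  df$.category <- y
  nnet::multinom(.category ~ ., data = df,
                 MaxNWts = (ncol(x) + 1L) * nlevels(y) + 10L,
                 maxit = 300L, trace = FALSE)
}

member_votes <- function(object, x) {
  df <- data.frame(x, check.names = FALSE)
  votes <- cbind(
    svm = as.character(predict(object$models$svm, x)),
    rf = as.character(predict(object$models$rf, x)),
    boosting = as.character(predict(object$models$boosting, x,
                                    type = "class")),
    maxent = as.character(predict(object$models$maxent, newdata = df))
  )
  rownames(votes) <- NULL
  votes
}

#' Majority vote over classifier ballots
#'
#' The plurality label wins; ties are broken by a fixed member-priority
#' order (maxent, then random forest, then SVM, then boosting): the winner is
#' the vote of the highest-priority member whose label is among the tied
#' leaders.
#'
#' @param votes Character matrix (rows = records) with columns named
#'   \code{svm}, \code{rf}, \code{boosting}, \code{maxent}.
#' @return Character vector of winning labels, one per row.
#' @export
majority_vote <- function(votes) {
  stopifnot(is.matrix(votes), all(ENSEMBLE_MEMBERS %in% colnames(votes)))
  apply(votes, 1L, function(row) {
    tab <- table(row)
    leaders <- names(tab)[tab == max(tab)]
    if (length(leaders) == 1L) return(leaders)
    for (member in VOTE_PRIORITY) {
      if (row[[member]] %in% leaders) return(row[[member]])
    }
    leaders[[1L]]  # unreachable: every leader is some member's vote
  })
}

#' Predict food categories with a fitted ensemble
#'
#' @param object A [food_ensemble()] fit.
#' @param newdata Character vector of food names, or a data.frame with a
#'   \code{name} column.
#' @param type \code{"class"} (default) for the majority-vote category,
#'   \code{"votes"} for the per-member ballot matrix.
#' @param ... Unused.
#' @return Character vector of categories, or a character matrix of votes.
#' @export
predict.food_ensemble <- function(object, newdata,
                                  type = c("class", "votes"), ...) {
  type <- match.arg(type)
  names_vec <- if (is.data.frame(newdata)) as.character(newdata$name)
               else as.character(newdata)
  x <- featurize_names(names_vec, object$vocabulary, tagger = object$tagger)
  votes <- member_votes(object, x)
  if (type == "votes") return(votes)
  majority_vote(votes)
}

#' @export
print.food_ensemble <- function(x, ...) {
  cat("<food category ensemble>\n")
  cat("  members:   SVM, random forest, boosting, maxent (majority vote)\n")
  cat("  trained on", x$n_train, "records;",
      length(x$vocabulary), "retained stems + 4 POS features\n")
  cat("  categories:", paste(x$levels, collapse = ", "),
      " | seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.food_ensemble <- function(object, ...) {
  cat("Food category ensemble (majority vote of 4 classifiers)\n\n")
  cat("Feature space:", length(object$vocabulary), "document-term stems",
      "(document frequency >", object$sparsity_threshold, "of corpus)",
      "+ 4 engineered POS/length features\n")
  cat("Training records:", object$n_train, "\n")
  cat("Category levels:", paste(object$levels, collapse = ", "), "\n")
  cat("Tie-break priority:", paste(VOTE_PRIORITY, collapse = " > "), "\n")
  invisible(object)
}

#' Precision, recall, and accuracy against reference labels
#'
#' One-vs-rest confusion counts per category: precision = TP/(TP+FP),
#' recall = TP/(TP+FN), accuracy = (TP+TN)/(TP+TN+FP+FN). A metric with a
#' zero denominator is reported as NA (undefined), not 0. Overall accuracy
#' is the fraction of records whose predicted category equals the reference.
#'
#' @param predicted,reference Character vectors of categories (same length).
#' @return A list of class \code{"food_eval"}: \code{per_category}
#'   (data.frame with columns category, tp, fp, fn, tn, precision, recall,
#'   accuracy) and \code{overall_accuracy}.
#' @examples
#' evaluate_classifier(c("r", "r", "d"), c("r", "d", "d"))
#' @export
evaluate_classifier <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  cats <- intersect(FOOD_CATEGORIES, union(predicted, reference))
  per <- do.call(rbind, lapply(cats, function(cat) {
    tp <- sum(predicted == cat & reference == cat)
    fp <- sum(predicted == cat & reference != cat)
    fn <- sum(predicted != cat & reference == cat)
    tn <- sum(predicted != cat & reference != cat)
    safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
    data.frame(category = cat, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = safe_div(tp, tp + fp),
               recall = safe_div(tp, tp + fn),
               accuracy = (tp + tn) / (tp + tn + fp + fn),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  structure(list(per_category = per,
                 overall_accuracy = mean(predicted == reference)),
            class = "food_eval")
}

#' @export
print.food_eval <- function(x, digits = 3, ...) {
  cat("Per-category metrics (one-vs-rest):\n")
  out <- x$per_category
  out$precision <- round(out$precision, digits)
  out$recall <- round(out$recall, digits)
  out$accuracy <- round(out$accuracy, digits)
  print(out, row.names = FALSE)
  cat("\nOverall accuracy:", round(x$overall_accuracy, digits), "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of the ensemble
#'
#' Splits the records into k folds stratified by category (the category
#' distribution is typically skewed, so unstratified folds can miss a class
#' entirely). Each record is tested exactly once and used for training k-1
#' times; the feature vocabulary is rebuilt from each training fold, so no
#' information leaks from the test fold.
#'
#' @inheritParams food_ensemble
#' @param k Number of folds, 2 <= k <= number of records.
#' @return A list of class \code{"food_cv"}: \code{fold} (fold id per
#'   record), \code{predicted} (out-of-fold prediction per record),
#'   \code{fold_accuracy}, \code{mean_accuracy}, and \code{metrics}
#'   (pooled [evaluate_classifier()] over the out-of-fold predictions).
#' @export
cross_validate <- function(data, k = 10L, seed = 1L,
                           sparsity_threshold = 0.01,
                           tagger = pos_tag_name) {
  stopifnot(is.data.frame(data), all(c("name", "category") %in% names(data)))
  n <- nrow(data)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of records", call. = FALSE)
  y <- as.character(data$category)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cat in unique(y)) {
    idx <- sample(which(y == cat))
    # cycle fold ids with a running offset so folds fill evenly across the
    # (possibly small) classes; k = n then yields leave-one-out
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }

  predicted <- character(n)
  fold_accuracy <- numeric(k)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- food_ensemble(data[!test, , drop = FALSE],
                         sparsity_threshold = sparsity_threshold,
                         seed = seed + f, tagger = tagger)
    predicted[test] <- predict(fit, data[test, , drop = FALSE])
    fold_accuracy[f] <- mean(predicted[test] == y[test])
  }
  structure(list(fold = fold, predicted = predicted,
                 fold_accuracy = fold_accuracy,
                 mean_accuracy = mean(fold_accuracy),
                 metrics = evaluate_classifier(predicted, y),
                 k = k, seed = seed),
            class = "food_cv")
}

#' @export
print.food_cv <- function(x, digits = 3, ...) {
  cat(x$k, "-fold stratified cross-validation (seed ", x$seed, ")\n",
      sep = "")
  cat("  fold accuracies:",
      paste(round(x$fold_accuracy, digits), collapse = " "), "\n")
  cat("  mean accuracy:  ", round(x$mean_accuracy, digits), "\n")
  invisible(x)
}
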