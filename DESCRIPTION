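Package: foodcoder
Title: Semi-Automatic Classification and FoodEx2 Description of Food Names
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for standardizing free-text food item names against the
    EFSA FoodEx2 food classification and description system. A majority-vote
    ensemble of four text classifiers (support vector machine, random forest,
    gradient boosting, maximum entropy) assigns each name one of the four
    food-chain categories (raw commodity, derivative, simple composite,
    aggregated composite) from a stemmed document-term matrix augmented with
    part-of-speech features. A probabilistic matcher describes names by
    ranking a coded food vocabulary with the product of the noun-set Jaccard
    index and a Laplace-smoothed Jaccard index over pooled adjective and verb
    lemma sets. Rule-based post-processing reconciles the two results.
    Includes a FoodEx2 code parser, a rule-based tagger/lemmatizer and Porter
    stemmer for short food names, and a seeded generator of synthetic coded
    vocabularies for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    xgboost,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
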