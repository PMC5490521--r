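# foodcoder

Semi-automatic classification and description of food item names according
to the EFSA **FoodEx2** food classification and description system.

Food composition and food consumption datasets can only be linked and
compared once their free-text food names carry FoodEx2 codes, and assigning
those codes by hand is slow and demands expert knowledge of the system.
`foodcoder` automates the two halves of that task for English food names:

1. **Classification** — predict the food-chain category of a name:
   raw commodity (`r`), derivative (`d`), simple composite (`s`), or
   aggregated composite (`c`).
2. **Description** — match the name to the most relevant entry of a coded
   food vocabulary and return its FoodEx2 code.

Rule-based post-processing then reconciles the two results, and the final
output is checked by the user — the system is semi-automatic by design.

## The models

**Classifier.** Each name is lowercased, stripped of punctuation and digits,
tokenized, and Porter-stemmed into a document-term count matrix; stems with
document frequency of at most 1% are dropped, and four engineered features
are appended: the number of nouns, adjectives, and verbs found by POS
tagging, and the name length in tokens. Four classifiers — a linear SVM, a
random forest, gradient-boosted trees, and a maximum-entropy (multinomial
logistic) model — vote on the category; the plurality wins, with ties broken
by a fixed member priority (maxent > RF > SVM > boosting).

**Matcher.** Both the query name and every vocabulary name are reduced to
lemma sets N (nouns), A (adjectives), V (verbs) by POS tagging and
lemmatization. Entries sharing at least one noun lemma with the query are
scored with the probability of the similarity event X = N (A + V):

```
P(N)   = |N1 ∩ N2| / |N1 ∪ N2|                      (Jaccard)
P(A+V) = (|(A1∪V1) ∩ (A2∪V2)| + 1) / (|(A1∪V1) ∪ (A2∪V2)| + 2)
W      = P(N) · P(A+V)
```

Adjectives and verbs are pooled so that "brown bread" and "browned bread"
can still match, and the Laplace (add-one) smoothing keeps the weight
positive when one name omits qualifiers. All entries tied at the top weight
are returned; the user picks one.

**Post-processing rules.** (1) r + a nature-changing process lemma in the
name → d; (2) r/d + composite match (s/c) → the match's category;
(3) s + match c → c; (4) c + match s → s. At most one rule fires.

## Worked example

Real FoodEx2 extracts are licensed, so the package ships a seeded generator
of structurally equivalent synthetic vocabularies (400 records by default,
category mix 47/33/14/6% for r/d/s/c):

```r
library(foodcoder)

vocab_df <- simulate_food_vocabulary(seed = 7)
fit      <- food_ensemble(vocab_df, seed = 7)
vocab    <- food_vocabulary(vocab_df)

fit
#> <food category ensemble>
#>   members:   SVM, random forest, boosting, maxent (majority vote)
#>   trained on 400 records; 69 retained stems + 4 POS features
#>   categories: r, d, s, c  | seed: 7

standardize_foods(c("mushroom soup", "buckwheat flour",
                    "cabbage chinese boiled", "barley grains"), fit, vocab)
#>                     name predicted_category    matched_name  ... weight n_matches final_category
#> 1          mushroom soup                  c   mushroom soup  ...    0.5         1              c
#> 2        buckwheat flour                  d buckwheat flour  ...    0.5         1              d
#> 3 cabbage chinese boiled                  d   cabbage fresh  ...    0.2         4              d
#> 4          barley grains                  r   barley grains  ...    0.5         1              r
```

A perfect name match scores 0.5, not 1: for identical term sets with u
pooled adjective/verb lemmas the weight is (u+1)/(u+2) — smoothing never
yields certainty. The matcher's components are exposed directly:

```r
q <- extract_term_sets("dried vine fruits (currants, raisins and sultanas)")
q
#> term sets
#>   nouns:      currant, fruit, raisin, sultana, vine
#>   adjectives: (empty)
#>   verbs:      dry

term_set_similarity(q, extract_term_sets("dried vine fruits (raisins etc.)"))
#> $p_nouns     0.6
#> $p_adj_verb  0.6666667
#> $weight      0.4
```

A command-line front end covering train / classify / describe / standardize /
make-fixture lives at `inst/cli/foodcoder.R` (see its header for usage).

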