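---
title: "Standardizing food names against FoodEx2: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing food names against FoodEx2: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodcoder)
```

## The problem

FoodEx2 is the European Food Safety Authority's standardized system for
classifying and describing foods. Every food gets a mandatory base-term code
(e.g. `A03BG` for orange nectar) optionally refined by facet descriptors —
`F09.A0EXH` (fortified with calcium), `F21.A07SE` (organic production) —
joined into a single string such as
`A03BG#F09.A0EXH$F10.A077L$F21.A07SE`. Before a food can be described, its
food-chain category must be known, because categories admit different
facets: raw commodity (`r`), derivative (`d`), simple composite (`s`), or
aggregated composite (`c`). Datasets that lack these codes cannot be linked
to other food data, and manual coding takes an expert on the order of
minutes per item.

`foodcoder` implements a semi-automatic pipeline: a text-feature ensemble
classifier proposes the category, a probabilistic matcher proposes the most
relevant entry of an already-coded vocabulary, and four deterministic rules
reconcile the two. The output is a proposal for a human to confirm, not a
replacement for one.

## Classification

### Features

Names are lowercased; punctuation and digits are removed; tokens are
Porter-stemmed (`dried` → `dri`). The corpus becomes a document-term count
matrix. Term columns whose document frequency is **at most** the sparsity
threshold (default 1% of the corpus) are removed — the retention rule is
strict (`df > threshold · N`), so in a 100-name corpus a stem present in
exactly one name is dropped. Four engineered columns are appended, computed
by POS tagging the raw (unstripped) name:

| feature | rationale |
|---|---|
| number of nouns | more nouns suggest a composite food |
| number of adjectives | qualifiers (fresh, frozen) mark specific forms |
| number of verbs | preparation processes mark derivatives/composites |
| name length (tokens) | long descriptions are rarely raw commodities |

Name length is counted in tokens rather than characters: the signal is "how
much is being said", and token counts are invariant to naming style
(abbreviations, long species names). Tagging runs on the lowercased original
name because commas and parentheses help the tagger; the punctuation-free
path feeds only the document-term matrix.

### The ensemble

Four classifiers are trained on identical feature matrices: a linear-kernel
SVM, a random forest (500 trees), gradient-boosted trees, and a
maximum-entropy model realized as multinomial logistic regression — the
standard realizations of these model families in R (`e1071`,
`randomForest`, `xgboost`, `nnet`). No hyperparameter tuning layer is
included; the realizations' defaults are used. Prediction is by majority
vote. Ties (2–2, or 1–1–1–1) are broken by a fixed priority order — maxent,
then random forest, then SVM, then boosting — reflecting the typical
single-model accuracy ranking of these families on short-text category
problems; a fixed order makes the vote deterministic.

All stochastic components (forest bootstrap, boosting, fold shuffling) are
driven by one user-supplied seed, so a fit and a cross-validation are exactly
reproducible.

### Evaluation

`evaluate_classifier()` computes one-vs-rest confusion counts per category
and from them precision TP/(TP+FP), recall TP/(TP+FN), and accuracy
(TP+TN)/(TP+TN+FP+FN). A metric whose denominator is zero (e.g. precision of
a never-predicted category) is reported as `NA`, never coerced to 0.
`cross_validate()` uses stratified k-fold splits: the category distribution
of real vocabularies is severely skewed (roughly 47/33/14/6% for r/d/s/c),
and unstratified folds can lose a class entirely. Fold ids are assigned
cyclically across classes with a running offset, so fold sizes stay balanced
even when a class has fewer members than folds, and `k = n` degenerates to
leave-one-out. The feature vocabulary is rebuilt inside each training fold,
so no term statistics leak from the test fold.

## Description

### Term sets and similarity

Both the query and every vocabulary name are reduced to three lemma sets by
POS tagging: nouns $N_i$, adjectives $A_i$, verbs $V_i$. Candidate retrieval
returns every vocabulary entry sharing at least one noun lemma with the
query. Each candidate is scored with the probability of the similarity event
$X = N\,(A+V)$, the two component events being independent:

$$P(N) = \frac{|N_1 \cap N_2|}{|N_1 \cup N_2|}, \qquad
P(A{+}V) = \frac{|(A_1 \cup V_1) \cap (A_2 \cup V_2)| + 1}
                {|(A_1 \cup V_1) \cup (A_2 \cup V_2)| + 2},$$

$$W = P(X) = P(N)\,P(A{+}V).$$

Adjectives and verbs are pooled because inflection moves words between the
two classes without changing meaning ("brown bread" / "browned bread");
lemmatization inside each set handles the rest ("apple dry" / "dried
apples"). The Laplace (add-one) estimate keeps $P(A{+}V)$ positive when one
name simply omits qualifiers — a frequent, benign mismatch in short food
names. Generic short-text similarity measures (character-level Jaccard,
KL-divergence variants) perform poorly on texts this short; the domain
structure — nouns carry the topic, adjectives/verbs carry the processing —
is what this score encodes.

Numerical corner cases are fixed as follows:

* both noun sets empty makes $P(N)$ a 0/0; it is defined as 0 (no topical
  evidence). Retrieval already requires a shared noun, so this arises only
  in direct `term_set_similarity()` calls;
* for identical sets with $u = |A \cup V|$ pooled lemmas the weight is
  $(u{+}1)/(u{+}2) < 1$: smoothing never yields certainty, and a "perfect
  match" with no qualifiers scores exactly 0.5;
* several entries can tie at the top weight; **all** are returned, sorted
  lexicographically for determinism, and the user chooses. The pipeline's
  automatic path uses the lexicographically first and flags the tie count.

Retrieval matches lemmatized nouns on both sides, not raw substrings: both
sides go through the same tagging and lemmatization, which is also the only
reading under which the bundled walkthrough weights (0.4, 0.5) come out of
the set arithmetic. A small stoplist (`etc`, `e.g.`, `i.e.`, `similar`,
`and`, `or`) removes filler tokens from term sets; without it, fillers like
"etc" would enter noun sets and distort the Jaccard denominators.

### The linguistic components

No stemmer, tagger, or lemmatizer for R is assumed at run time; the package
authors all three:

* **Porter stemmer** — the classic five-step suffix-stripping algorithm,
  tested against canonical published example pairs.
* **POS tagger** — rule-based with Penn-style tags, designed for the
  grammar of food names, which are overwhelmingly noun phrases: the default
  tag is noun; `-ed`/`-en`/`-ing` morphology plus a lexicon of
  cooking-process bases yields verbs; a lexicon of food qualifiers yields
  adjectives; function words are tagged non-content. The tagger is injected
  behind a function argument (`tagger =`), so any Penn-tagset tagger — or a
  deterministic stub in tests — can replace it.
* **Lemmatizer** — irregular-form dictionary plus morphological rules
  (plural stripping for nouns; `-ied` → `-y`, e-restoration, and
  consonant-undoubling for verbs, validated against the process-verb
  lexicon: `canned` → `can`, `baked` → `bake`).

The tagger's known failure mode is proper names with verb-like morphology
("nanking" tags as a gerund); this perturbs individual weights but rarely
the ranking, and is the accepted cost of a deterministic, dependency-free
tagger.

## Post-processing rules

The description result corrects the classifier:

1. classified `r` but the name's adjective/verb lemmas contain a
   nature-changing process (canning, smoking, frying, baking, ...) → `d`;
2. classified `r` or `d` but the best match is composite (`s`/`c`) → the
   match's category;
3. classified `s`, best match `c` → `c`;
4. classified `c`, best match `s` → `s`.

Exactly one rule's consequence is applied. When rules 1 and 2 both hold
(raw prediction, process verb present, composite match), rule 2 wins:
evidence that the food *is* a specific composite dominates the weaker
inference that some process was applied. This makes the rules idempotent
for a fixed match category. The process lexicon ships as an editable
plain-text file (one lemma per line, `inst/extdata/process_lexicon.txt`)
seeded with common nature-changing processes; users holding the full
official process list can supply it via `read_process_lexicon()`.

## Synthetic vocabularies

Real FoodEx2 extracts are licensed and cannot be redistributed, so
`simulate_food_vocabulary()` generates structurally equivalent corpora:
bare commodity wordings for `r` ("barley grains"), commodity + process
product for `d` ("buckwheat flour"), two-ingredient product templates for
`s` ("apple compote"), dish templates for `c` ("mushroom soup"), each with a
grammar-valid synthetic code. Defaults are a 400-record corpus — a
desk-scale stand-in for the multi-thousand-entry real extract — with the
skewed 47/33/14/6% category mix of real category extracts. The wording
pools make categories nearly separable from term features, which mirrors
how strongly conventionalized real food-name wording is at small scale; a
`noise` argument injects random commodity words to blur the signal for
stress tests.

What passing on these fixtures shows: the mechanics — feature construction,
voting, retrieval, scoring, rules — are correct and deterministic. What it
does not show: accuracy on real vocabularies, which contain synonymy
("tinned"/"canned"), translation artifacts, culture-specific foods, and
names absent from the vocabulary altogether. Published experience with this
pipeline on real data shows precisely those failure modes dominating the
error budget; the rule layer recovers some but not all of them.

## Problem sizes and runtime choices

The test suite trains ensembles on the 400-record fixture (seconds per fit)
and cross-validates with k = 10, its mean accuracy frozen as a regression
bound at the value established at first release (1.0 on this near-separable
fixture — a mechanics check, not a claim about real data). Oracle-equivalence
properties (retrieval and top-weight versus brute-force scans) run over 50
independently seeded small vocabularies. The acceptance script rebuilds the
two bundled walkthrough neighborhoods (7 records each) and recomputes their
weights through the full pipeline.

## Known limitations

* English names only; no translation layer.
* The rule-based tagger is deterministic but shallow; a statistical tagger
  can be injected where available.
* Foods absent from the vocabulary yield an empty match (reported as such),
  not a newly composed facet string.
* Facet semantics are not validated against the official term catalogue;
  the code parser checks grammar, not catalogue membership.
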