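---
title: "Cost-sensitive hierarchical abstract triage: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive hierarchical abstract triage: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitriage)
```

## The problem

Biocuration databases such as the Immune Epitope Database retrieve thousands
of candidate abstracts from broad PubMed keyword queries. Before any manual
curation happens, each abstract must be (a) screened for relevance — does it
contain curatable epitope-specific data at all? — and (b) routed into a
disease-area category so that the right curator sees it. The categories form
a tree: seven broad Level-1 disease areas, then increasingly specific Level-2
and Level-3 sub-categories (an Autoimmunity abstract may be a Diabetes
abstract, and within Diabetes a GAD-antigen abstract). Four of the Level-1
areas (Allergy, Autoimmunity, Infectious Disease, Transplantation) are funded
curation priorities; abstracts routed into the low-priority areas (Cancer,
HIV, Other) receive no further human review, so a high-priority abstract
misrouted into a low-priority bucket is *lost* — by far the most expensive
mistake the system can make. epitriage implements the full pipeline, and a
synthetic corpus generator so every stage can be exercised and tested without
network access.

## The model, stage by stage

### Document representation

Only titles and abstracts are used. Text is lowercased, split on
non-alphanumeric characters, filtered of PubMed stopwords, length-1 tokens
and pure digits, and bag-of-words counted. Terms occurring in fewer than
three documents are dropped (`min_df = 3`). For each classification task the
100 terms with the highest information gain against that task's binary
labelling are selected (`k_features = 100`), computed on that task's training
documents only — never on held-out folds. A document becomes a vector of
`count × ln(N/df)` TF-IDF weights over the selected terms, scaled to unit
Euclidean length by default.

Two of these choices deserve a note. First, an "information gain threshold of
100" is implemented as *top-100 terms ranked by IG*: information gain is
bounded by the class entropy (at most 1 bit for a binary split), so a
threshold *value* of 100 is not meaningful, while a selection *size* of 100
is standard practice. Second, the IDF base (natural log), raw-count TF and
unit-length normalisation are fixed, documented defaults — any monotone
variant works, and all three are exposed as arguments for users who want
different conventions.

### Base classifiers and the ensemble

Every scoring task uses a soft-margin linear SVM (`C = 1`, the era-standard
configuration for text categorisation; fitted with libsvm via e1071). For
robustness each task trains a *leave-one-subset-out ensemble*: the training
set is split into ten disjoint label-stratified subsets, ten SVMs are trained
each with one subset withheld, and at prediction time the ten margins are
averaged. Raw margins (not calibrated probabilities) feed the combiner.
Stratification of the subsets is a deliberate choice the original protocol
leaves open: on heavily imbalanced tasks an unstratified split can produce a
member with no positives at all.

A multinomial Naive Bayes classifier with Laplace smoothing (`alpha = 1`) is
included purely as the historical baseline for the relevance gate; the test
suite checks the directional claim that the SVM ensemble matches or beats it
on separable corpora.

### The relevance gate (Level 0)

The curatability classifier is an ensemble like any other, but its decision
threshold is calibrated: on pooled out-of-fold cross-validation scores, the
cutoff sweep keeps every cutoff reaching the target sensitivity (default
95%, matching the inherent disagreement rate between two human screeners)
and picks the one maximising specificity. The calibrated threshold is stored
in the bundle and reused for prediction. On synthetic data at default signal
strength the classes separate almost perfectly, so the chosen threshold sits
in the score gap and held-out sensitivity is typically ~100%; the target is
a *floor*, and the acceptance checks treat it as one — a calibrator is not
penalised for exceeding a sensitivity floor.

### Hierarchical category assignment

For every sibling set in the taxonomy (the seven Level-1 areas; each parent's
Level-2 children; each Level-3 set), one-vs-rest ensembles are trained with
negatives restricted to *same-parent siblings* — a Diabetes classifier sees
only other Autoimmunity abstracts as negatives, not the whole corpus. Each
category's classifier performs its own feature selection. Routing is greedy
top-down: a document's Level-2 decision happens inside whichever Level-1
branch it was assigned, even if that assignment was wrong; there is no global
path optimisation. Branch irregularities are honoured: branches can skip
Level 2 (children sit directly at Level 3) or terminate early and receive no
deeper assignments.

Sibling sets too small to train honestly fall back to majority-class
assignment (logged in the bundle). A category is considered trainable when it
has at least `max(min_examples, ~m·k/(k−1))` documents, so that every
cross-validation training fold retains the `m` positives the ensemble split
needs.

### The cost-sensitive combiner

Within a sibling set, a document's per-category ensemble scores form its
*score profile*. A small multilayer perceptron — one hidden layer of
`floor(K/2)` sigmoid units (minimum 2) for `K` categories, softmax output —
maps the profile to category probabilities. The phrase "hidden layers equal
to the number of categories divided by two" in the WEKA-era configuration is
read as hidden *units*: a three-layer-deep stack for a seven-input combiner
is not a plausible reading, and WEKA's wildcard syntax configures units. The
combiner is trained on pooled out-of-fold profiles (so it never sees scores
from classifiers trained on the same documents) by online gradient descent
with momentum — 500 epochs, learning rate 0.3, momentum 0.2, the defaults of
the era's reference implementation — from a seeded uniform(−0.5, 0.5)
initialisation, with inputs standardised. Training is bit-reproducible given
the seed.

Cost sensitivity acts twice, and each mechanism can be switched off
independently because the original protocol does not say which was used:

* **training-time instance weights** — a document of true class *i* is
  weighted by the ratio of row *i*'s cost-matrix row-sum to the mean row-sum,
  so expensive-to-lose classes dominate the loss;
* **decision-time expected cost** — the predicted category minimises
  `sum_i p_i C[i, j]` over columns *j* instead of maximising probability.

Two cost-matrix builders cover the pipeline's needs. At Level 1 the
*priority matrix*: 0 on the diagonal, 1 between two high-priority categories,
0.2 between two low-priority ones, **5** for a true-high document predicted
low, and 1 for the reverse. The true-low→predicted-high cost is not part of
the published core (it lives in supplementary material not reproduced here);
1 — an ordinary misclassification — is the default, consistent with the
observed behaviour that cost sensitivity *increases* low→high errors while
suppressing high→low ones. At Levels 2–3, when an "Other"/"Various"
catch-all is among the siblings, the *catch-all matrix*: predicting a
specific document into the catch-all costs 5, pulling a catch-all document
into a specific category 0.2, specific↔specific confusion 1. The cost
between two catch-alls (OTH→VAR) is likewise unpublished; it defaults to
0.2, treating it like low-importance confusion. All entries are arguments.

### Evaluation machinery

AUC uses the Mann–Whitney pair-counting formulation (average ranks; ties
count ½), with ROC points swept over midpoints of sorted unique scores plus
±∞; a property test holds the trapezoidal integral and the rank formula to
1e-12 of each other. Cross-validation is stratified: 10-fold at Levels 0–1,
5-fold deeper. The flat-vs-hierarchical harness trains each category twice —
negatives restricted to siblings vs all curatable documents — on shared folds
and compares the per-category AUC columns with a classical paired two-sided
t-test (which refuses zero-variance differences rather than reporting a
meaningless statistic). Percentages are reported at full precision and
rounded to one decimal only for display.

The package also ships, as plain-text fixtures, the published evaluation
tables of the IEDB triage study (the 287-document Level-1 confusion matrix,
per-branch Level-2/3 correct counts, Level-0 gate counts on the
1,388-document independent benchmark, and the seven paired
flat/hierarchical AUCs). `benchmark_report()` re-derives every headline
figure from those raw counts with the package's own analytics — accuracy
94.4/93.9/82.1% at Levels 1–3, gate sensitivity 95.3% and specificity
67.3%, AUC means 0.983 vs 0.992 with paired p = 0.009 — which pins the
analytics to published ground truth.

## The synthetic corpus generator

Real training corpora for this task are distributed as PMID lists whose
abstract text must be fetched, so the package carries a generator that
emulates the statistical structure the classifiers rely on, not the surface
of English text:

* a **background vocabulary** of 2,000 terms with Zipf (1/rank)
  probabilities, shared by all documents — 2,000 is a realistic desk-scale
  effective vocabulary once stopwords and rare words are removed;
* a disjoint **signal vocabulary** of 20 uniform terms per taxonomy node,
  plus one for "curatable" content generally and one for uncuratable
  content. Uniform (rather than Zipf) signal keeps the information-gain
  arithmetic in oracle tests tractable;
* each document draws Poisson(150) tokens; a token is background with
  probability `alpha = 0.7`, otherwise drawn from one of the document's
  label-path nodes. Uncuratable documents mix background with the
  uncuratable vocabulary only;
* class imbalance mirrors the production corpus: 75% uncuratable, and the
  Infectious Disease leaf weighted 5×, making it the dominant Level-1 class.
  The default configuration yields ≈2,000 documents (≈500 curatable) — the
  scale at which the recovery checks are run.

All randomness flows from one mandatory seed through a single RNG stream in
a fixed document order, so a corpus is reproducible byte-for-byte from its
JSON manifest alone.

Three presets are *purpose-built hard cases*, each constructed to exhibit
the phenomenon its check needs (their parameters were chosen so the
phenomenon exists, and are not tuned thereafter):

* `confusable_config()` — a rare high-priority category sharing 90% of its
  signal with a 10× larger low-priority neighbour, at `alpha = 0.9`. A
  cost-blind combiner loses a substantial number of the rare category's
  documents to the big one; the priority matrix should reclaim most of them
  (at the price of more errors in the opposite, cheap direction — the same
  trade the production system reported).
* `nested_config()` — two branches of three leaves, each leaf sharing half
  its signal with a *cross-branch* twin, `alpha = 0.9`. Sibling-negative
  (hierarchical) training never meets the twin; flat training must separate
  it. This reproduces the direction of the published flat-vs-hierarchical
  comparison at desk scale.
* `catchall_config()` — three specific categories plus an OTH bucket whose
  vocabulary is 90% borrowed from its siblings, `alpha = 0.9`; heterogeneous
  as real "Other" categories are, it attracts over-prediction until the
  catch-all matrix penalises it.

### What passing these tests shows — and what it does not

The generator produces exchangeable documents with conditionally independent
tokens: no syntax, no burstiness, no correlated terms, no label noise, and
signal vocabularies that are exactly disjoint unless deliberately overlapped.
Passing recovery checks on such corpora demonstrates that the pipeline's
machinery — feature selection, ensembles, combiner, cost logic, routing —
is implemented correctly and behaves in the documented directions. It does
*not* demonstrate the AUC levels achievable on real abstracts, where signal
is weaker, correlated and noisy; the published benchmark fixtures are the
only real-data anchor in the package, and they exercise the analytics, not
the classifiers.

## Numerical and degenerate-input choices

* Feature selection ties (equal IG) break lexicographically, so selection is
  a pure function of its inputs.
* The threshold sweep uses midpoints between sorted unique scores with ±∞
  endpoints; a document scoring exactly the threshold is called curatable.
  If only the accept-everything cutoff reaches the sensitivity target, −∞ is
  returned with a warning rather than an error.
* Expected-cost ties pick the smallest canonical category index.
* An all-zero score vector stays all-zero under normalisation; an empty
  document tokenises to an empty sequence and scores the bias/prior.
* Single-child sibling sets assign their only label without a classifier;
  single-class corpora disable the Level-0 gate with a logged note.
* Analysis problem sizes used by the checks: recovery runs use the ≈2,000-
  document default corpus; the preset experiments use 440 (confusable), 360
  (nested) and 200 (catch-all) documents with 5-fold profiles and 200
  combiner epochs — sizes at which every stochastic check is comfortably
  reproducible on one CPU.

## Known limitations

* Greedy routing propagates Level-1 mistakes downward by design (the
  production pipeline behaves the same way); no global path optimisation.
* Raw SVM margins feed the combiner uncalibrated; their scale differs
  between tasks, which the combiner's input standardisation absorbs.
* The bundled taxonomy carries only the published core of the category tree
  (Autoimmunity's Level-2 set and Diabetes' Level-3 set); production trees
  must be supplied as config.
* No stemming, n-grams or embeddings — bag-of-words is the modelled method.
* MEDLINE parsing covers the PMID/TI/AB tags this pipeline consumes, not the
  full NLM record grammar.
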