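---
title: "Classifying nonmedical use and side effects of methylphenidate in tweets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying nonmedical use and side effects of methylphenidate in tweets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimtweet)
```

## The surveillance problem

Methylphenidate is a stimulant prescribed for attention deficit
hyperactivity disorder and narcolepsy. Because it enhances focus, reduces
appetite and can produce euphoria, it is also taken without a prescription —
to cram for exams, to stay up all night, to lose weight, or recreationally —
and it carries a well-known side-effect profile (appetite loss, insomnia,
anxiety, palpitations, and others). Surveys under-measure nonmedical use
because respondents conceal it; spontaneous-report pharmacovigilance systems
capture side effects but say little about misuse. Public Twitter posts that
mention the drug by name offer a complementary signal: people describe their
own use in first person, in near real time.

`stimtweet` implements a complete, testable pipeline for this surveillance
task. Given a corpus of tweets mentioning methylphenidate (by generic or
brand name), it classifies each tweet for two binary outcomes — *nonmedical
use* and *side effects* — and aggregates classified tweets into monthly
trend tables. Because public tweet corpora on this topic cannot be
redistributed, the package also contains a synthetic-corpus generator that
reproduces the statistical structure the pipeline assumes, so the whole
chain is exercised end to end by the test suite.

## The model

Each tweet is reduced to a 23-dimensional count vector built from curated
lexicons:

* **Personal nouns** (4 features): first-, second-, third-person and
  "other person" tokens (family and friends), counted on raw lowercase
  tokens *before* stop-word removal, because pronouns are stop words.
  Nonstandard spellings ("im", "iam", "ur") and truncated contraction forms
  ("i'", "he'") are included; the truncated forms match raw tokens by
  prefix, so "i'm" and "he's" count. Each token counts in at most one
  category, checked in list order. These features separate first-hand
  experience from news, lyrics and third-party reports.
* **Nonmedical-use terms** (7 features): general misuse words, alternative
  motives (studying, partying, dieting, ...), overdose, alternative routes
  of administration (snorting, injecting, ...), drug seeking, obtaining, and
  coingestion with alcohol or other drugs. Matching is on Porter-stemmed
  content tokens, so "snorted" and "snorting" both hit the stem "snort".
* **Medical-use terms** (1 feature): ADHD/narcolepsy treatment vocabulary,
  which indicates medical rather than nonmedical use.
* **Side-effect terms** (9 features): general terms plus eight symptom
  groups (appetite, sleep, psychiatric, heart, gastrointestinal,
  neurological, sweating, eye).
* **Sentiment score** (1 feature): the signed count of opinion-lexicon
  words over raw tokens (+1 per positive word, -1 per negative word), since
  tweets about misuse or adverse effects tend to be emotionally polarized.
  "wtf" is added to the negative list by default.
* **URL flag** (1 feature): tweets linking to news or study results are
  rarely first-hand experience.

The nonmedical-use classifier sees 14 of these features (personal nouns,
nonmedical terms, medical terms, sentiment, URL); the side-effects
classifier sees 15 (personal nouns, side-effect terms, sentiment, URL).
Each classifier excludes the other task's term group, mirroring the
feature-group structure of the task design.

Classification uses a support vector machine with a radial basis function
kernel. Positive tweets are rare (about 1 in 20), so the loss is
class-weighted with inverse weights `w_c = N / (2 n_c)`, which equalizes
the total weighted mass of the two classes. Features are standardized with
training-set statistics (zero-spread columns pass through unscaled) before
the kernel is applied. The decision threshold is the SVM's natural sign
rule; there is no probability calibration.

## Tunable parameters

* `cost_grid`, `gamma_grid` (`svm_config()`): the cost parameter penalizes
  margin violations; gamma is the inverse kernel width. Defaults are the
  standard log-scale grids `2^(-2..10)` and `2^(-9..1)`. Selection is by
  exhaustive grid search maximizing the mean positive-class F1 over
  stratified cross-validation folds; F1 replaces accuracy because under a
  5% prevalence the all-negative classifier is 95% accurate and useless.
  Folds where a model predicts no positives contribute F1 = 0; ties break
  toward the smaller cost, then the smaller gamma, preferring the smoother
  model.
* `cv_folds` (default 10): stratified by label, assignment fixed by the
  configuration seed.
* Reported performance uses **pooled out-of-fold predictions**: each tweet
  is predicted by the model that did not train on it, and one confusion
  matrix is pooled over all folds. Resubstitution (training-set) metrics
  are available by predicting the fitted model on its own inputs, but the
  pooled protocol is the default everywhere because resubstitution numbers
  are optimistic. Precision, recall, accuracy and F1 come from the pooled
  confusion counts; the negative-class F1 treats the negative class as the
  class of interest. Ratios with zero denominators are reported as 0 and
  flagged rather than returned as NaN, so ablation tables stay stable under
  extreme imbalance.
* Display rounding is half-up: metrics to 3 decimals, percentages to 2.

## Preprocessing choices

Tokenization lowercases, removes URLs (recording their presence), strips
`#` from hashtags (hashtag words often carry content, e.g. "#adhd") and the
`@` sigil from mentions, and splits on non-word boundaries while keeping
internal apostrophes. The content stage then removes stop words (a
versioned 174-word snowball-style list shipped with the package — packaging
the list keeps results identical across environments), drops purely numeric
tokens (alphanumerics like "2nite" are kept), strips apostrophes and stems
with the Porter algorithm. The stemmer is implemented in the package and
tested against the canonical example pairs of the algorithm's definition.

Personal-noun matching runs on raw tokens before stop-word removal; all
other lexicon matching runs on content stems. The pronoun lists could never
match after stop-word removal, so this split is forced; it is recorded here
as a package design decision rather than a property of any particular
historical dataset.

A design point that was genuinely open: subfeature counts (7 nonmedical,
9 side-effect dimensions) are kept as separate features rather than summed
per group. Separate dimensions preserve information, and group-level
ablation is well defined either way since a group's columns are removed
together.

## The synthetic corpus generator

`generate_corpus()` emulates the corpus structure the pipeline assumes:

* roughly 5.2% of tweets positive for nonmedical use and 5.5% for side
  effects, with 0.3% positive for both;
* every positive contains 1–3 injected lexicon terms of its task's group
  (surface inflections whose Porter stems hit the lexicon, e.g. "snorted");
  side-effect positives additionally carry a negative sentiment word half
  the time;
* positives are first-person with probability 0.9 and carry URLs with
  probability 0.05; negatives are first-person with probability 0.3, carry
  URLs with probability 0.4, and contain news/lyrics-like filler;
* one drug mention per tweet from the 14 generic/brand search terms;
  timestamps uniform over August 2018 – July 2019 (UTC);
* remaining length (8–20 tokens per tweet) is filled from a 500-word
  pseudo-word noise vocabulary constructed to collide with no lexicon stem,
  sentiment word, stop word or drug name. Tweet length and noise-vocabulary
  size are package choices; they are not estimates of any real corpus.

The generator is deterministic given its configuration, and it logs every
injected term so tests can assert the causal link between injection and
feature counts.

**What the generator does not emulate.** Real tweets are natural language:
sarcasm, misspellings beyond the lexicons' curated variants, ambiguous
first-hand claims, lyrics quoting drug names, and — critically — everyday
words that collide with lexicon stems ("I *need* to buy a *double*
espresso") occur constantly. By default the generator's negatives contain
no lexicon collisions at all, which makes the synthetic task close to
separable: the classifiers reach near-perfect pooled cross-validated F1 on
default corpora. Passing tests on this corpus therefore demonstrate that
the pipeline machinery is correct (features detect what was injected,
weighting and tuning behave, the ablation attributes performance to the
right feature group) — they do not demonstrate that these F1 levels are
attainable on real Twitter data, where reported F1 for comparable tasks is
in the 0.5–0.75 range. The `p_confounder_neg` option plants
lexicon-colliding everyday words in a chosen fraction of negatives for
robustness exploration; at rates of 0.2 and above the contaminated
negatives become statistically indistinguishable from weak positives and
precision degrades sharply, which is the expected behavior of a
lexicon-count model, not a defect of the implementation.

## Ablation

`run_ablation()` retrains the task classifier once per feature group with
that group's columns removed before scaling, each run with its own
hyperparameter tuning, and evaluates every run with pooled out-of-fold
predictions on the same seed-fixed folds. On synthetic corpora the
"without term features" row collapses (only the term counts carry the
injected signal), and the other rows stay near the full model — the
expected attribution.

## Numerical and degenerate-input conventions

* Constant feature columns pass through scaling unchanged (no division by
  zero); the URL column, for example, can be constant in small corpora.
* Single-class label vectors are an error everywhere (weights, folds,
  training), reported as such rather than producing degenerate fits.
* Cohen kappa is `(p_o - p_e) / (1 - p_e)` with marginal-product expected
  agreement; when both annotators give identical constant labels
  (`p_e = 1`), kappa is defined as 1.
* Duplicate removal folds case and whitespace and keeps the earliest
  timestamp; search-term filtering is case-insensitive substring matching,
  chosen to mirror collection-time drug-name search (so "concerta" inside a
  longer token still matches).
* `split_train_test()` takes either a fraction (`round(fraction * N)`) or
  an exact `train_size`, the latter reproducing externally reported split
  sizes exactly.
* Month bucketing is UTC.

## Problem sizes used by the test suite and acceptance script

The packaged test suite and `scripts/acceptance.R` run the full chain on
corpora of 400–5000 tweets with a coarsened power-of-two grid
(cost `2^(-2..10)` in steps of 4x, gamma `2^(-9..1)` in steps of 4x, 10
folds). These sizes are the package's chosen study scale for routine
verification; the full default grids are available through `svm_config()`
for production analyses.

## Known limitations

* Lexicon-count features cannot detect side effects outside the curated
  symptom groups, and a fixed lexicon dates quickly as slang shifts.
* The classifier sees one tweet at a time; context from a user's earlier
  tweets (e.g. a disclosed ADHD diagnosis) is out of scope.
* Input is assumed English and pre-filtered; there is no language
  detection, spelling correction, or emoji handling.
* Tweet counts are not prevalence: trends over months reflect posting
  behavior as much as consumption.
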