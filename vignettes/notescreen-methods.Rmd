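---
title: "Methods: pre-referral abuse screening from clinical note text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-referral abuse screening from clinical note text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Child physical abuse is routinely evaluated by specialist child-abuse
pediatrics (CAP) teams at referral hospitals, but the clinicians who first
see a child — emergency physicians, nurses, social workers at community
sites — must decide whether to refer with far less support. `notescreen`
implements a screening pipeline that predicts, from the free text of a
patient's chart, whether a CAP evaluation would classify the case as
abuse-positive, **using only the notes written before the CAP team became
involved**. The temporal restriction is the scientific core of the design:
a model allowed to read the specialist work-up would be answering a
different (and useless) question.

Because the records such a screen would train on are protected health
information, the package is built around a synthetic EMR generator that
reproduces the *statistical* structure the analysis depends on. Every
pipeline stage is exercised and audited against that generator, including
an exact Bayes reference for what any classifier could achieve on it.

## Pipeline

1. **Truncation.** Each patient's time-ordered notes are cut at the first
   note whose author role marks a CAP clinician (any role prefixed
   `CAP-`, or an explicit role set). The CAP note itself and everything
   after it are discarded (`truncate_at_cap()`).
2. **Cleaning and merging.** The surviving notes are concatenated in time
   order and cleaned: punctuation replaced by spaces, whitespace
   collapsed, lowercased, then tokens containing digits, single-character
   tokens and stop-list tokens dropped, in that order (`build_corpus()`).
   The fixed order makes mixed tokens like `3am` resolve
   deterministically (the digit rule removes them before the length
   rule could see `am`).
3. **Exclusion filters.** Records are excluded, in a fixed precedence
   (`filter_cohort()`): unclassified outcome label; fewer than 2 notes
   remaining; corpus over 100,000 cleaned words; empty corpus. Each
   record is tallied once, under the first matching rule, and the report
   always conserves the input count.
4. **Encoding.** Three representations (`fit_tfidf()`/`apply_tfidf()`,
   `load_embedding()`/`encode_embedding()`, `encode_rules()`), below.
5. **Classification.** Multilayer perceptrons trained under a repeated
   stratified k-fold protocol (`run_cross_validation()`), with
   architecture selection (`select_architecture()`) and a ridge logistic
   baseline on identical folds (`train_logistic_baseline()`).
6. **Interpretation.** Gradient saliency-frequency maps
   (`saliency_frequency_map()`), leave-one-out rule ablation
   (`rule_loo_sensitivity()`), and a frozen-encoder audit of an external,
   distribution-shifted corpus (`external_corpus_screen()`).

### The stop list and negations

The default stop list is the standard NLTK English list **minus**
`no`, `not` and `nor` (`default_stop_words()`). Negation words carry
decisive clinical meaning — "no acute distress" and "acute distress"
should not collapse to the same encoding — and saliency analyses of
bag-of-words abuse classifiers consistently rank "no" among the most
influential words, which is only possible if it survives cleaning.
Whether to keep negations is exposed as configuration rather than
asserted, since published pipelines are ambiguous on this point.

### Encodings

**BOW-TFIDF.** The variant is pinned explicitly so it can be tested
against a brute-force oracle: for vocabulary word $w$ and corpus $c$,

$$\mathrm{weight}(w, c) = \mathrm{tf}(w, c)\,
  \Bigl(\ln\frac{1 + N}{1 + \mathrm{df}(w)} + 1\Bigr),$$

followed by L2 row normalization (all-zero rows stay zero). This is the
smoothed form that is the de-facto standard in text-classification
toolkits. The vocabulary, $\mathrm{df}$ and $N$ come from the corpora
the model was fitted on and are never updated at encoding time, so a
test corpus cannot leak into the encoder. When a `max_features` cap is
set, words are kept by descending collection frequency with alphabetical
tie-breaks.

**Word embeddings.** A word2vec-style text table maps each token to an
$n$-vector; out-of-vocabulary tokens get deterministic pseudo-random
vectors with components uniform on $[-0.5/n, 0.5/n]$, keyed by
`(word, oov_seed)` so repeated runs are identical. Documents are pooled
by the arithmetic mean of token vectors (sum pooling is available); the
document representation fed to the classifier is not standardized in the
literature this follows, so mean pooling was fixed as the simplest
length-invariant choice and exposed as a parameter. The encoder reports
per-document *coverage* — the fraction of tokens found in the table —
because unrepresentative embeddings (general-domain tables applied to
pediatric notes) are the known failure mode of this encoding: roughly
half of clinical-corpus tokens are typically missing, and performance
collapses accordingly.

**Rules-based (RB).** A clinician-curated lexicon of polarized phrases
(the study-scale default is 88: substantially more positive-concern than
negative-concern phrases, because the absence of a finding is rarely
charted). Each corpus becomes a vector over $\{-1, 0, 1\}$: 1 if a
positive-concern phrase occurs as a contiguous run of cleaned tokens, 0
if a negative-concern phrase occurs, and −1 if the phrase is absent —
the distinct "not found" value prevents an inapplicable rule from
masquerading as reassurance. Phrases are cleaned with the same pipeline
as the corpora, so "History of domestic violence." matches the token
run `history domestic violence`. The full published lexicon was never
released; `starter_lexicon()` ships a small synthetic starter file and
the TSV format accepts any user lexicon.

### The classifier and training protocol

The MLP is implemented directly in matrix code (fully-connected ReLU
hidden layers, optional inverted dropout, one sigmoid output; binary
cross-entropy; ADAM with the conventional $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$). Keeping the forward and
backward passes in-package is what makes exact input gradients — and
hence the saliency analysis and the gradient-based tests — possible.

Training (`train_mlp()`) holds out a random 10% of the training rows as
an *internal validation set*, fixed across epochs within a run, trains
for exactly the configured number of epochs, and then **restores the
weights from the epoch with the highest internal-validation accuracy**
(earliest epoch on ties). Training deliberately proceeds past the
overfitting inflection; the restoration step is the overfitting guard.
Defaults: 25 epochs (bag-of-words and rules inputs; embedding inputs
typically need 50), batch size 32, learning rate $10^{-3}$, Glorot
uniform initialization. All randomness (validation split, weight
initialization, batch order, dropout masks) derives from one integer
seed.

Cross-validation (`run_cross_validation()`) builds a stratified k-fold
partition (default 10) from a master seed — every record appears in
exactly one test fold — and trains each architecture `n_repetitions`
times per split (default 10), with the repetition index perturbing the
training seed through a deterministic integer hash. Architecture
selection picks, per architecture, the best model of each split by test
accuracy (ties: higher AUC, then lower repetition index), averages those
per-split accuracies, and returns the architecture with the highest
average (ties: fewer parameters, then lexicographic id). The default
grid is eight architectures: widths $\{64\}, \{128\}, \{64,32\},
\{128,64\}$ crossed with dropout $\{0, 0.5\}$ — a configurable stand-in
for an unpublished hyperparameter table.

The logistic baseline is ridge-penalized (glmnet, $\alpha = 0$, fixed
small $\lambda$, standardized predictors) and fitted per split on
exactly the rows the MLPs trained on, so the comparison isolates what
the hidden layers add. With all-constant predictors it degrades to the
intercept-only limit (predicted probability = training prevalence)
rather than erroring.

### Metrics and statistics

`compute_metrics()` thresholds at 0.5 with $\geq$ (a probability of
exactly 0.5 is called positive) and reports the confusion counts,
accuracy, sensitivity, specificity, PPV and F1; any ratio with a zero
denominator is `NA` and named in an `undefined` field, never silently
zero. AUC is the concordance probability — a random positive outscores
a random negative, ties counted one half, computed by the rank formula —
which equals the trapezoidal area under the ROC step curve; the test
suite asserts that equality to $10^{-9}$ and cross-checks against an
independent ROC implementation.

Group comparisons use Welch's unequal-variance two-tailed t-test
(the compared groups — correct versus incorrect classifications — have
very unequal sizes, so the pooled-variance form would be wrong more
often than right) and Pearson's chi-squared without continuity
correction on r×c tables after dropping all-zero rows and columns.
`probability_distribution_comparison()` bins two probability samples
into 10 equal-width bins on [0, 1] (configurable; the binning used in
the literature is undescribed), drops bins empty in both groups, and
applies the chi-squared test to the 2×bins table.

### Interpretation

*Saliency* of a word for a record is
$|\partial p / \partial x_w|$ — the gradient of the predicted
positive-class probability with respect to the word's input feature,
evaluated at the record's encoding by exact backpropagation (the test
suite checks it against central finite differences). Saliency is
reported only for words actually present in the record: the question is
how changing a word *in the corpus* would move the classification, and
gradients of absent words are not interpretable in that sense. Per
record the top-k (default 50) salient words are kept, ties broken
alphabetically for determinism; frequencies are then accumulated by
*ground-truth* class and the top 50 per class reported.

*Rule ablation* invalidates each rule in turn (column set to −1 for all
test records), recomputes accuracy at the threshold, and reports the
delta; weights are untouched — it is an inference-time sensitivity
analysis, and rules with exactly zero delta are listed separately.

*External audit.* An encoder fitted on internal data only is frozen and
applied to external texts cleaned by the same pipeline and filtered to a
word-count window (5000–7000 by default usage, the scale of typical
internal corpora). Since the external corpus is assumed to contain no
true positives, the fraction classified positive is a false-positive
rate under dataset shift; per-rule prevalence ratios
(external/internal fraction of records containing the phrase, 0/0
reported as undefined) localize which phrases drive it.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the features the analysis assumes,
and nothing more:

- **Labels**: Bernoulli with prevalence 0.55 by default, the
  positive-class share typical of cohorts already referred for abuse
  evaluation.
- **Phrase presence**: per lexicon phrase, class-conditional Bernoulli,
  independent across phrases given the class. Defaults: positive-concern
  phrases present in 22% of positive and 15% of negative records,
  negative-concern phrases in 10% and 18%. Each phrase is individually
  weak — single charted phrases are never diagnostic — but with a
  study-scale 88-phrase lexicon the aggregate log-likelihood-ratio
  discriminability sits near an AUC of 0.90
  (`bayes_reference_auc()`), the scale at which real pre-referral
  screens operate. An early draft with stronger per-phrase contrasts
  made the cohort perfectly separable, which no reported screening
  cohort is; the defaults were re-chosen once on that ground.
- **Record shape**: at least one pre-CAP note (count 1 + negative
  binomial, heavy right tail), exactly one CAP-authored note (role
  `CAP-MD`/`CAP-NP`), then zero or more later notes; strictly increasing
  ISO-8601 timestamps; author roles drawn from
  {RN, MD, SW, CAP-MD, CAP-NP}.
- **Text**: Zipf-distributed background tokens (vocabulary disjoint by
  construction from phrase tokens and from the leakage sentinel);
  pre-CAP corpus length log-normal with median 6000 words, the order of
  magnitude of real merged corpora. Present phrases are inserted
  verbatim by *replacing* a random non-overlapping slice of background
  tokens, so insertion preserves the length distribution.
- **Leakage sentinel**: a reserved token injected into every
  CAP-or-later note and nowhere else. Any occurrence of it downstream of
  truncation is proof of leakage; the test suite greps for it.
- **Leakage-audit mode** (`phrase_location = "post_cap"`): all indicator
  phrases are placed in CAP-and-later notes instead, so a correctly
  truncating pipeline sees pure noise. This mode is run with prevalence
  0.5, because the chance-level accuracy band it is judged against is a
  binomial band around 0.5 and a signal-free classifier on an imbalanced
  cohort sits at the majority-class rate by construction.

`generate_external_corpus()` emits already-clean token streams of
controlled length whose phrase prevalence follows a user-supplied shift
vector — emulating an adult-ICU-style audit corpus in which clinical
phrases occur in very different proportions than in pediatric abuse
records.

`bayes_reference_auc()` scores presence vectors by the exact
log-likelihood ratio
$\sum_j x_j \ln(p_{1j}/p_{0j}) + (1-x_j)\ln\bigl((1-p_{1j})/(1-p_{0j})\bigr)$
and returns the concordance AUC between the class-conditional score
distributions: the ceiling for any classifier on the rules encoding.
With ≤2 phrases all presence patterns are enumerated exactly (ties get
half weight); otherwise Monte Carlo with a configurable number of draws.
Presence probabilities of exactly 0 or 1 are rejected (infinite
log-likelihood ratio).

### What the generator does *not* emulate

No clinical prose, templated EMR structure, de-identification artifacts,
inter-phrase correlation, or within-class heterogeneity. Consequently,
passing tests show that the *pipeline machinery* is correct — truncation
is airtight, encoders match their formulas, the training protocol
recovers signal up to its information-theoretic ceiling and not beyond —
but say nothing about how well any encoding represents real clinical
language. Two visible artifacts of the simplification: the rules
encoding outperforms bag-of-words on synthetic cohorts (the generative
signal *is* exactly phrase presence, which RB reads off directly),
whereas on real records the reverse was reported; and at a few hundred
records the MLP's advantage over ridge logistic regression is modest,
as deep models are data-hungry.

## Numerical choices and degenerate inputs

- Seeds: every stochastic operation takes an explicit integer seed;
  derived seeds come from a deterministic integer hash kept below
  $2^{31}$. Identical configuration + seed reproduces byte-identical
  output everywhere.
- Ties: collection-frequency ties in vocabulary truncation and saliency
  ties break alphabetically; best-epoch ties break earliest; model-
  selection ties break by higher AUC, lower repetition, fewer
  parameters, lexicographic id — all stated in the function docs.
- Degenerate inputs: empty corpora encode to zero vectors (TF-IDF,
  embeddings) or all −1 (rules); single-class label vectors make AUC
  `NA` (flagged) and training error out; non-finite training loss stops
  with a diagnostic rather than returning garbage; all-zero contingency
  tables and sub-2×2 tables are rejected.
- The probability threshold comparison uses $\geq 0.5$ throughout, so a
  maximally uncertain record counts as a positive screen — the
  conservative direction for an abuse screen.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` run the generator at desk
scale, chosen as the smallest sizes at which the audited properties are
statistically meaningful: leakage and signal-recovery cohorts of 400
patients under 10-fold cross-validation; the acceptance study at 500
patients (88-phrase lexicon, ~6000-word corpora, 2 architectures × 10
splits × 2 repetitions per encoding); the protocol-arithmetic check at
its full 10 × 10 × 2 = 200-model grid on a toy matrix. The headline
protocol (10 splits × 10 repetitions × 8 architectures on ~900 records)
is the configured default of `cv_config()` and `default_architectures()`
and runs unchanged, just longer.

## Known limitations

- The word-embedding path ships a loader and encoder but no embedding
  table; real embeddings are external artifacts, and the encoding's
  known coverage problem on clinical text applies.
- Saliency is defined for bag-of-words inputs at the feature level; it
  is not implemented for pooled-embedding inputs, where per-word
  attribution through the mean is not well defined.
- The generator's independence assumptions (phrases conditionally
  independent given class) make `bayes_reference_auc()` exact for the
  generator but only an analogy for real records.
- No confidence intervals on AUC and no multiple-testing correction are
  provided, matching the analysis conventions this package follows.
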