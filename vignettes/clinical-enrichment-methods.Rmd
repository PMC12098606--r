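---
title: "Methods: two-stage clinical data enrichment from free-text reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage clinical data enrichment from free-text reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Oncology biomarkers that drive real-world-evidence studies — hormone-receptor
status, HER2, mismatch-repair status, FIGO and TNM staging, tumour grade —
are routinely recorded only inside free-text pathology reports. Manual
abstraction does not scale, and sending report text to external services is
usually impossible because the text carries patient-identifiable information
(PII). `clinenrich` implements a two-stage enrichment pipeline whose outputs
are *closed-vocabulary by construction*: whatever the input, the only thing
emitted per report and feature is a class label from a fixed per-biomarker
vocabulary plus two confidence scores, so no free text can leak.

## The model

**Stage 1 — extractive question answering.** Each clinical feature carries a
natural-language question ("What is the p53 status?"). An extractive backend
maps (report, question) to an *answer span*: a substring of the report with
0-based half-open character offsets and a confidence in $[0,1]$. Because the
backend may only return verbatim substrings — the package wraps every
backend and verifies `text == substr(context, start+1, end)` on every call —
hallucinated values are structurally impossible. Unanswerable reports yield
the empty span. The packaged reference backend is rule-based: it finds each
alias occurrence (e.g. `her2`, `her-2`), scans a 60-character window after
it (never across a sentence boundary) for a value drawn from the feature's
surface-form lexicon, and returns that value span with confidence 0.95 for
an exact surface-form match and 0.5 for a bare in-range integer of a bounded
numeric feature. Transformer QA models can be plugged in through
`transformer_adapter()`, which defines span confidence as the product of the
start- and end-token probabilities renormalised against the no-answer score
(that definition is this package's choice; it is monotone in model
certainty).

**Stage 2 — routing and classification.** Blank spans and spans with QA
confidence below 10% are routed straight to the reserved class
`not_present`. Surviving span texts are classified into the feature's closed
vocabulary by one of two few-shot classifiers over deterministic character
n-gram hashing embeddings (3–5-grams hashed into 1024 buckets,
L2-normalised; texts are lower-cased, whitespace-collapsed, edge-punctuation
stripped, and padded with one boundary space so one-character classes embed
non-trivially):

* the **prototype classifier** scores each class by the maximum cosine
  similarity to that class's labelled example embeddings and predicts the
  argmax, with a softmax over class scores as its confidence. Max rather
  than centroid is the default because surface forms are multi-modal ("g3"
  and "high grade" both realise grade 3, and their centroid resembles
  neither); a centroid mode is available.
* the **contrastive few-shot classifier** first learns a linear refinement
  map $W$ (initialised at the identity) by full-batch gradient descent on
  the pair loss
  $y\,(1-\cos(Wa,Wb))^2 + (1-y)\,\max(0,\cos(Wa,Wb)-m)^2$
  over sampled same-class ($y=1$) and different-class ($y=0$) example pairs,
  then fits a ridge-penalised multinomial logistic head on the re-normalised
  refined embeddings. This reproduces the two-stage structure of few-shot
  sentence-embedding fine-tuning (contrastive refinement, then a
  classification head) with a linear refiner, which keeps fitting
  deterministic, CPU-scale and dependency-free. Realising the refinement as
  a linear map over frozen base embeddings rather than deep weight updates
  is a deliberate design decision.

When a report mentions a feature several times, each candidate span is
classified and the most clinically severe class wins, mirroring how such
reports are annotated.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `qa_confidence_threshold` | 0.10 | routing cut-off; below it a span becomes `not_present` |
| rule-backend `window` | 60 chars | value scan range after an alias, truncated at sentence end |
| embedder `dim`, `ngram` | 1024, 3–5 | hashing buckets and character n-gram range |
| `softmax_temperature` | 1 | sharpness of the prototype confidence |
| contrastive `margin` | 0.25 | cosine above which negative pairs are penalised |
| contrastive `pairs_per_example` | 20 | sampled pairs per labelled example (half positive) |
| contrastive `epochs`, `learning_rate` | 10, 0.01 | refinement-map gradient descent |
| head `lambda` | 1e-4 | ridge penalty of the logistic head |

The 10% routing threshold applies to QA confidence only; the classifier
confidence is always emitted so users can apply their own downstream
thresholds.

## Vocabularies and severity orders

The packaged registry holds 23 features: 18 endometrial/breast/staging
features and 5 lung features. The published class table for this feature
set has no row for TTF1; the registry gives it a positive/negative
vocabulary by analogy with the other lung immunostains and documents that
as an inference. Bounded numeric features expose one class per integer of
their printed range (blast cell percentage 0–100, ER/PR scores 0–8)
alongside their categorical classes.

Severity orders are a documented package choice (only the resolution *rule*
— keep the most severe — is externally specified): stage- and grade-like
features ascend with stage (FIGO 1 < 1a < … < 4b, TNM with X least severe
after `not_present`), and binary markers rank the disease-indicating class
highest. That rule puts `deficient` above `intact` for MMR, `present` above
`absent` for the invasion features, and — because protein *loss* is the
disease-indicating state — `absent` above `present` for the four MMR
proteins. For ER/PR the order is negative < 0 … 8 < positive; for blast
percentage, `no excess` < `an excess` < 0 … 100 (a stated percentage is
treated as more informative than the vague categorical). All orders are
overridable in the registry configuration. `not_present` is the severity
minimum everywhere and can never win a resolution.

## The synthetic corpus generator

Real NHS pathology reports cannot ship with the package, so
`generate_corpus()` emulates their relevant structure: word counts are
log-normal (default `sdlog` 0.8, with `meanlog` solved so the expected
count is 339.9), clipped to 7–3213 words — a right-skewed length model
typical of clinical text; sentences occasionally gain a `[redacted]` token,
imitating upstream de-identification; positive reports embed mentions drawn
from the same surface-form lexicon the rule backend scans (`style_noise`
interpolates from canonical forms to abbreviations, phrase variants and a
deterministic one-typo misspelling); impossible-answer reports either omit
the feature, state that staining "has been requested", or redact the value;
and multi-mention reports insert two classes and label the more severe.
Positive counts are exact (not binomial) per feature, so balanced
evaluation splits always exist.

What the generator does *not* emulate: real report macro-structure
(headers, specimen blocks), clinical co-occurrence between biomarkers,
free-form prose around mentions, and genuinely out-of-lexicon spellings.
Passing tests on synthetic data therefore demonstrate the pipeline's
*contracts* (closed vocabulary, no-hallucination, routing, severity
resolution, metric correctness) and its behaviour under controlled noise —
not clinical-grade accuracy on real reports, which depends on the QA model
plugged into stage 1.

## Evaluation protocol

Per feature, a balanced test set of 50 positively identifiable and 50
impossible-answer reports is scored as percent accuracy over the closed
vocabulary, with macro precision/recall/F1 over truth-present classes
(macro is this package's choice; the averaging convention is not externally
fixed). Across features, scores are summarised as mean ± a Student-t 95%
interval, $\bar x \pm t_{n-1,0.975}\, s/\sqrt n$ with $n$ the feature
count — the t-form (not normal-z) is pinned by reproducing four printed
accuracy intervals exactly at two decimals in the test suite. Error
structure is decomposed two ways (truth-impossible vs truth-positive
errors; errors assigned the impossible class vs a substantive class), and
interrater agreement uses Cohen's kappa with the convention that a
degenerate chance agreement of 1 yields kappa 1 under perfect agreement
and 0 otherwise.

The adaptability experiment refits the classifier from training subsets of
5/10/20/50/100 reports (nested within each of 5 seeded permutations —
nesting reduces between-size variance and is a package choice; only
"random sampling" is externally specified), evaluates on a fixed balanced
split, and aggregates per size across features with the same t-interval.
The packaged experiment runs three lung features on a 200-report synthetic
corpus, which is the scale at which the accuracy-vs-training-size plateau
is already visible (at zero style noise the curve saturates near 100% by
20 training reports).

## Numerical choices and degenerate inputs

* Classifier ties break to the first class in schema order — deterministic
  and documented; an all-zero-similarity query therefore falls to the first
  class at uniform confidence.
* An empty span is the sentinel (`""`, offsets −1/−1); empty texts embed to
  the zero vector and are never sent to a classifier (routing catches them
  first).
* A class with a single example contributes only negative pairs to
  contrastive sampling (warning, not an error); one-class example sets are
  valid for the prototype classifier and an error for the contrastive one.
* The refinement-map fit guards cosines with an epsilon on vector norms and
  fails loudly on non-finite loss; zero epochs reduce the model exactly to
  a logistic head on base embeddings.
* All randomness (corpus generation, splits, pair sampling) flows from
  explicit seeds through a deterministic seed-derivation helper, and the
  RNG state of the caller is always restored; the full pipeline is
  bit-reproducible.

## Problem sizes used by the packaged checks

The test-suite and acceptance-script scales are the package's own choices:
18 features × 100 noise-free reports for the exactness check, six
word-style features at style noise 0.3 for the prototype-vs-contrastive
comparison, three lung features × 200 reports × 5 permutations for the
learning curve, 10,000 mixed synthetic and adversarial reports for the
closed-vocabulary property, and 1,000/500 random instances for the
brute-force oracle comparisons.

## Known limitations

* The rule-based backend is an honest reference implementation, not a
  clinical-grade extractor; features whose values precede the alias
  ("strongly ER positive") or sit in tables are out of its reach. The
  backend contract is the intended substitution point for a fine-tuned QA
  model.
* Bounded numeric features are classified over integer classes; fractional
  values ("7.5") match their integer prefix.
* The generative-baseline module ships prompt assembly, output parsing and
  a mock backend only; running a real generative model is a user-supplied
  hook, and the packaged extraction-echo mock cannot severity-resolve
  multi-mention reports (it echoes the first mention).
* Cohen's kappa is exercised on synthetic annotator pairs; the package has
  no access to real dual-annotated data.
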