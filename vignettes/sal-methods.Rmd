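---
title: "Methods: detecting and typing self-acknowledged limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and typing self-acknowledged limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmine)
```

## The task and the model

A self-acknowledged limitation (SAL) is a weakness of a study that its
authors state themselves, typically in the discussion or a dedicated
limitations subsection of an RCT report. `salmine` treats the problem as
two chained sentence-classification tasks.

**Stage 1 — SAL sentence detection.** Candidate sentences come from the
abstract plus every section whose top-level or innermost header contains
one of seven limitation-signalling keywords (*discussion, limitation,
weakness, conclusion, caveat, shortcoming, drawback*; case-insensitive
substring match, so "Study Limitations" and "Strengths and weaknesses"
both qualify). The classifier input is the sentence concatenated with
its two headers through a separator marker — the headers carry strong
positional evidence (a sentence under "Study limitations" is far more
likely to be a SAL). A text encoder maps this composite to a fixed-width
vector; a single-logit linear head with a sigmoid is trained under
binary cross-entropy. The decision threshold defaults to 0.5, and the
comparison is `>=` at the boundary.

**Stage 2 — SAL type classification.** Each SAL sentence receives a set
of limitation types from a fixed two-level taxonomy: 15 top-level and 24
fine-grained categories, each fine category under exactly one parent
(`SampleSize` under `UnderpoweredStudy`). At fine granularity the label
space also contains the 15 top-level names, because annotators may use a
top-level label when no sub-category fits, giving 39 labels. The head is
a one-hidden-layer perceptron (tanh) followed by a softmax, so
per-sentence label scores form a probability distribution; multi-label
gold sets are converted to a uniform target distribution over the gold
labels for the cross-entropy objective. A sigmoid head with per-label
binary cross-entropy is available behind `head = "sigmoid"` for users
who prefer the conventional multi-label formulation; the softmax route
is the default because it pairs naturally with the thresholding below.

**Dynamic per-label thresholding.** A single global cut-off is a poor
fit when label frequencies span two orders of magnitude. For every label
independently, `fit_thresholds()` sweeps a candidate grid (default 0.01
to 0.99 in steps of 0.01) and keeps the threshold maximizing that
label's binary F1 on the development split, breaking ties toward the
smallest threshold (the most permissive optimum, which favours recall on
rare labels). A label unseen in the development gold cannot be tuned;
its threshold falls back to the grid maximum with a warning, making the
label effectively rule- or fallback-driven. At decoding time a label is
emitted when its probability reaches its threshold; if nothing passes,
the default fallback emits the argmax label, because every stage-2 input
is by construction a SAL sentence and an empty type set is implausible.
`fallback = "empty"` disables this.

**The Funding rule.** The `Funding` class is rare and (in the data the
taxonomy was built on) occurs only on multi-label sentences, which are
excluded from augmentation seeds, so the classifier has little to learn
from. A deterministic rule supplements it: a sentence gains `Funding`
when any of its tokens stems to `financ` or `fund` under the bundled
suffix-stripping stemmer ("funding", "funds", "financed", "financing"
all match; "fundamental" does not, because the *whole stem* must equal
the cue). The literal stem pair `finance`/`fund` can be supplied instead
for users who want exact-token semantics. The rule is a set union, so it
never removes classifier predictions.

## The encoder contract

Classifiers are agnostic to the text representation: any object with an
`encode(texts) -> matrix` function of fixed width satisfies the
contract, which is how contextual transformer encoders (a
domain-pretrained biomedical BERT's pooled classification vector) plug
in. The bundled default is a deterministic feature-hashing bag-of-words
encoder: lowercase word tokens and adjacent bigrams hashed into 512
buckets with a platform-stable polynomial hash, L2-normalized per
sentence. It is not a contextual model and will not capture negation or
long-range syntax, but it is fast, dependency-free and fully
deterministic, which makes every downstream stage trainable and
reproducible on one CPU. Training uses plain minibatch SGD with
momentum 0.9; the seed in `train_config()` fixes the weight
initialization and the per-epoch shuffling, so two runs with the same
config are bit-identical.

Default hyperparameters (`train_config()`): 40 epochs, learning rate
0.5, batch size 32, hidden width 64, token budget 128. These are
repository choices tuned once for the hashing encoder on synthetic
fixtures; they are not published values, and users plugging in a
contextual encoder should expect to lower the learning rate
substantially.

## Agreement machinery

Annotation quality for set-valued sentence labels is measured with
Krippendorff's α in the coincidence-matrix formulation, which
accommodates any number of annotators and missing annotations: units
with fewer than two annotations are dropped; observed disagreement
weights each within-unit ordered pair by `1/(m_u - 1)`; expected
disagreement pools all pairable values. The distance is pluggable and
plays the role of the squared-difference term directly — the package
does not square the supplied distance, and documents this choice because
conventions differ; pass a squared metric if you want the other
convention. The default is MASI, `1 − J·M`, with Jaccard overlap `J` and
monotonicity weight `M` = 1 (identical sets), 2/3 (strict containment),
1/3 (overlap without containment), 0 (disjoint). Two empty sets are
identical (distance 0). Token-level pairwise agreement uses Cohen's κ
over category-vs-category labels including an outside label `"O"`, with
κ defined as 1 when both annotators are constant and equal (pe = 1).

## Class-balancing augmentation

`build_plan()` computes, per class, the count *n* of training sentences
carrying the label and the deficit `max(0, 70 − n)` against the minimum
class size of 70. Multi-label sentences count toward *n* but are
excluded from generation seed pools (an augmentation method conditioned
on one label cannot disentangle the cues of several), and `Funding` is
ineligible outright — it is served by the rule instead. Four filling
strategies share the plan:

- **Oversampling** duplicates single-label originals uniformly with
  replacement up to the target.
- **EDA** applies one operator per variant — synonym replacement (word
  count preserved), random insertion, random deletion (never below one
  word), random swap — at a per-word rate of 0.1 (one operator per
  variant; both are repository defaults).
- **Dual-view generation** prompts a generator either with the seed
  sentence's RAKE keywords (Input View) or with the label name alone
  (Output View), 10 candidates per seed. The production generator (a
  soft-prompt-tuned encoder–decoder) sits behind the same contract as
  the bundled deterministic template generator, which fills
  label-specific clause templates so that the whole chain runs offline.
- **Consistency filtering** keeps candidates whose label under a filter
  classifier (trained on the original, pre-augmentation data) equals the
  intended label. Filtering trades precision of the synthetic pool
  against coverage of rare classes: frequent classes pass easily while
  rare-class candidates are exactly the ones an imperfect filter
  rejects, which starves the classes augmentation is meant to rescue.
  For that reason the unfiltered Output-View preset (`"dual-output"`) is
  the recommended default in `run_end_to_end()`.

`balance()` draws exactly `deficit` samples per class uniformly without
replacement from that class's pool; a short pool is exhausted with a
warning and nothing is ever fabricated or relabeled, so under the
default long-tailed distribution the rarest classes can legitimately
end below 70 — visible in the plan and in the warning stream.

## Significance testing and profiling

Paired classifier comparisons use McNemar's test on per-item
correctness: the uncorrected `χ² = (b−c)²/(b+c)` on the discordant
counts, switching to the exact two-sided binomial when `b + c < 25`
(the uncorrected form is used deliberately, because it is the 2-category
limit of the Bhapkar statistic via `B = M/(1 − M/n)`). For multi-class
paired outcomes the Bhapkar test of marginal homogeneity is provided,
with multi-label prediction sets encoded as composite classes (sorted
labels joined canonically; the empty set maps to a reserved class). Its
covariance matrix uses the consistent estimate that does not assume
homogeneity; a singular matrix falls back to a generalized inverse with
the rank as degrees of freedom, with a warning. Metrics over repeated
randomly-initialized runs (five in the reference protocol) are
summarized as mean ± sample SD.

`profile_corpus()` applies the full two-stage pipeline to a corpus and
reports the type distribution at two resolutions: sentence-level counts
(percentages summing to 100 over predicted label instances) and
document-level counts (a type counts once per article). Per-article
means carry normal-theory 95% confidence intervals using the t
distribution on per-article values — a pragmatic choice for count data
that is approximately symmetric at these means.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces sectioned articles
(Abstract/Introduction/Methods/Results/Discussion/Study limitations)
whose limitation-related sections contain template-generated SAL
sentences with known labels, at the structural statistics of the
annotated corpus the taxonomy was developed on: about 4.8 SAL sentences
per article (drawn as 2 + Poisson(2.8)), about 1.15 labels per SAL
sentence (15% of sentences combine two clause templates in one
sentence), and a long-tailed top-level distribution whose three most
frequent classes (`Population` ≈ 17.6%, `OutcomeMeasures`,
`UnderpoweredStudy`) and two rarest (`Setting`, `Funding`) follow the
published sentence-level counts, with the remaining classes
interpolated to a comparable tail (the bundled distribution file's
`provenance` column records stated vs interpolated). Each top-level
type owns five clause templates built around cue tokens unique to that
type, and each type with children has one representative fine-grained
category realized with probability 0.5.

This buys two properties that real text does not have: **cue
separability** (a bag-of-words model can, in principle, classify the
fixtures perfectly, so pipeline smoke tests have a known achievable
target) and **span-exactness** (gold labels are produced by projecting
the generator's own clause spans through the package's segmentation and
projection code, so BRAT round trips are exact by construction).
Consequently, passing tests on synthetic corpora demonstrates that the
machinery is correct — extraction, training, thresholding, evaluation,
profiling compose without information loss — but says nothing about
accuracy on real RCT prose, where cues are shared across types, negated,
or absent. Scores near 1.0 on fixtures must not be read as expected
real-world performance; published F1 scores for this task sit around
0.82 (sentence stage) and 0.70 (type stage, micro) with a
domain-pretrained transformer encoder and the authors' annotated corpus.

## Numerical and procedural choices

- Offsets are 0-based and end-exclusive everywhere (BRAT convention);
  sentence records carry both section-frame and document-frame offsets.
- The sentence segmenter splits at `.`/`!`/`?` runs followed by
  whitespace and an upper-case letter or digit, with a small
  abbreviation guard (`e.g.`, `vs.`, `fig.` ...); it is deliberately
  pluggable — any segmenter honouring the offset contract can replace
  it.
- Article splitting floors the development and test ratios and gives
  every remainder article to the training split, so 200 articles at
  (0.6, 0.2, 0.2) yield exactly 120/40/40.
- Threshold ties go to the smallest grid point; the grid lives strictly
  inside (0, 1).
- `α` with a constant-zero distance returns 1 by convention (no observed
  disagreement); zero expected but nonzero observed disagreement is an
  error rather than a silent division.
- Problem sizes in the test suite and the acceptance script — 200-article
  corpora, 60-article model fixtures, 200 randomized oracle instances
  per statistic — were chosen as the smallest sizes at which the checked
  properties are stable; they complete in well under a minute each on a
  single CPU.

## Known limitations

- The bundled encoder is lexical; real-world use should plug a
  contextual encoder into the encoder contract.
- The template generator cannot produce genuinely novel phrasings, so
  augmentation experiments on synthetic corpora measure bookkeeping
  (counts, determinism, filtering behaviour), not linguistic diversity.
- Fine-grained fixtures realize one representative sub-category per top
  type; the remaining sub-categories are exercised through the taxonomy
  and validation tests, not through generated text.
- Whether thresholds should be applied to softmax probabilities or to
  pre-softmax scores is ambiguous in the literature this follows;
  softmax probabilities are the default here, and the sigmoid head is
  the escape hatch.
- Whether `Other` may co-occur with specific labels on one sentence is
  unspecified in the data model; the package allows it and surfaces such
  sentences in validation output rather than rejecting them.
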