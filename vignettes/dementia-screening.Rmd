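---
title: "Screening dementia from free conversation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening dementia from free conversation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what is modeled,
which knobs matter, what the synthetic data can and cannot tell you, and
where the design was genuinely open.

## The screening problem

A subject talks freely with an interviewer for about ten minutes; only the
subject's speech is transcribed, fillers included. The question is whether
that transcript alone carries enough signal to discriminate dementia from
non-dementia (healthy controls plus mild cognitive impairment), using the
session's neuropsychological scores only to *define* the ground-truth label,
never as features.

### Rule-based session labels

Labels are assigned per session, because a subject seen repeatedly can
convert (e.g. MCI to dementia) between visits. The rules combine the
Clinical Dementia Rating (CDR, staged on {0, 0.5, 1, 2, 3}), the Mini-Mental
State Examination (MMSE, 0–30) and the delayed story recall of the Wechsler
Memory Scale-Revised (LM II), whose impairment cutoff depends on education:
2 points for 0–9 years, 4 for 10–15, 8 for 16 or more. "At or below the
cutoff" is read inclusively (`lm2 <= cutoff`) because the clinical
definition is phrased as "scored N points or less"; "above" is strict.

Three patterns define dementia (severe global decline; preserved MMSE with
amnestic impairment; questionable CDR with low MMSE and amnestic
impairment), one defines non-dementia (CDR ≤ 0.5 with MMSE ≥ 24), and every
other pattern falls back to the recorded clinical diagnosis. A fallback
without a recorded diagnosis raises an error rather than silently dropping
the session — data problems should surface. The rule engine was verified
exhaustively against a brute-force evaluator over the full
CDR × MMSE × LM II grid.

Sessions are excluded for age under 45, GDS ≥ 10 (depressive
pseudodementia), any missing required field (including education, since the
LM II cutoff needs it), or strong dialect. The clinical source lists these
filters without an order; we fix the reporting precedence age → GDS →
missing → dialect so that a session with several triggers is always reported
the same way.

Only *typical* sessions train models: dementia with CDR ≥ 1, MMSE ≤ 23 and
LM II at/below cutoff; MCI-type non-dementia with CDR 0.5, MMSE ≥ 24, LM II
at/below cutoff; control-type non-dementia with CDR 0, MMSE ≥ 24, LM II
above cutoff. The training criteria are strictly nested in the label rules
(checked by enumeration), so no session can train against its own label.

## Document embedding

A transcript is tokenized into morphemes with aligned part-of-speech tags.
The default tokenizer splits on whitespace and reads an optional
`token/POS` suffix; any function with the same contract (for instance an
adapter around a Japanese morphological analyzer) can be substituted. POS
tags are treated as opaque symbols throughout.

Two embedding channels are trained with a skip-gram-style negative-sampling
objective (5 noise words per positive pair, noise distribution proportional
to unigram frequency^0.75):

* a **morpheme channel** (default 150 dimensions) over the token stream;
* a **POS-bigram channel** (default 50 dimensions) over the stream of
  consecutive tag pairs, carrying syntactic-transition information
  independent of vocabulary.

Their concatenation is the 200-dimensional feature vector. The original
vectorization this re-specifies is proprietary, so two documented modes are
provided and neither claims to match it:

* `mode = "dbow"` (default): one trainable vector per document predicts the
  document's tokens (a distributed bag-of-words paragraph vector). New or
  truncated documents are embedded by gradient steps against the frozen
  output matrix, seeded from a hash of the token sequence so inference is
  reproducible and independent of batch position. A document whose token
  sequence equals a training document reuses the trained vector outright,
  which makes "truncating beyond the document length changes nothing" an
  exact identity rather than an approximate one.
* `mode = "average"`: skip-gram word vectors (window 5, randomly shrunk per
  position) averaged per document.

Training is single-threaded C++ driven by an internal xorshift generator:
identical corpus, configuration and seed give bitwise-identical vectors.
Defaults `epochs = 40`, `min_count = 1` and `learning_rate = 0.025`
(linearly decayed) suit corpora of tens to hundreds of documents; with very
large corpora `min_count` should rise. Degenerate documents are defined
away from errors: a single-token document has no POS bigrams and embeds to
the zero vector on that channel, so truncated prefixes always remain
scorable.

The TF-IDF baseline uses raw-count tf, `idf = ln((1+N)/(1+df)) + 1` and
L2-normalized rows, fitted on training documents only.

## Classifiers

Five families satisfy one contract — fit on labeled vectors, score new
vectors with a probability of dementia in [0, 1], predict at 0.5:

* **dnn** — input, three hidden ReLU layers (128/64/32), sigmoid output;
  inverted dropout 0.2; Adam at 1e-3; batch 16; at most 200 epochs with
  early stopping on validation loss (patience 10, best weights restored).
  The hidden-layer count is fixed at three by construction. The reference
  study tuned its network automatically but published neither widths nor
  search space; our defaults are chosen for small-sample stability and an
  optional seeded randomized search (`tune_dnn`, ≤ 25 trials) over widths,
  dropout and learning rate stands in for a full tuner.
* **gnb** — Gaussian naive Bayes with variance smoothing
  (`var + 1e-9 · max(var)`) so constant features stay finite.
* **lr** — logistic regression with an L2 (ridge) penalty, default
  λ = 0.01: with 200 features and ~50 training rows the unpenalized
  likelihood is degenerate under separation.
* **svc** — RBF support-vector classifier; scores are a logistic link on
  the sign-aligned decision margin, keeping the ROC well defined without
  randomized probability calibration.
* **xgb** — gradient-boosted trees (100 rounds, depth 3, η = 0.1), single
  thread.

All fits are deterministic at a fixed seed; the caller's RNG stream is
saved and restored. No class weighting is applied — prevalence imbalance is
handled downstream by the vote threshold.

## Validation architecture

For each held-out session: every other session of the same subject is
removed (a subject's repeat visits would otherwise leak idiolect into
training), every non-typical session is removed, and the remaining pool is
split 10 times into training and validation at 3:1 with class proportions
preserved (allocation exact up to one sample per class, at least one sample
of each class in both parts). The split seed is
`base_seed + (sample_index − 1) · n_splits + i`, recorded so any individual
model can be replayed. Ten models vote; votes ≥ k predicts dementia, so
k = 0 predicts dementia for everyone and reproduces the prevalence
baseline. The threshold maximizing pooled accuracy is selected, smallest k
on ties.

Selecting the threshold on the same pooled predictions it is evaluated on
is optimistic; `cv_config(vote_threshold =)` supports a pre-registered
operating point, and the package's own zero-separation checks use the
majority vote (k = 5) for exactly that reason.

AUC is computed per model slot: slot j's ROC pools every held-out session's
j-th score; the headline figure is the mean of the `n_splits` slot AUCs.
The AUC is the trapezoidal area, implemented as the midrank (Mann–Whitney)
statistic, so exact ties contribute 1/2 and an all-constant score vector
gives 0.5.

Subgroup comparisons (all vs training-criteria subset, male vs female,
age < 75 vs ≥ 75) use the Pearson χ² on correct/incorrect counts with the
Yates continuity correction, each cell clamped at zero
(`max(|O−E|−0.5, 0)² / E`). The continuity-corrected form is the one that
reproduces all three published subgroup statistics from their printed
counts; the uncorrected form does not. The "all vs criteria" comparison
deliberately uses overlapping groups (the subset is counted in both rows),
again because that is the arithmetic the published table performs. The
length/accuracy curve truncates every transcript to 100-letter prefixes,
re-embeds each prefix, and scores it with the same ten models that judged
the full document, at the already-selected threshold.

A "letter" is any non-whitespace Unicode character; whitespace is a
transcription artifact. Punctuation and long-vowel marks count — the
clinical source does not define the unit formally, so the convention is
fixed and documented here. Truncation carries interleaved whitespace
without counting it, so truncated text remains tokenizable.

## The synthetic cohort generator

The real cohort is private, so the generator emulates the statistical
structure the analysis depends on:

* per-subject class (dementia fraction defaulting to the analyzed
  prevalence 193/432 ≈ 0.447) and 1–3 repeat sessions (defaults 55/40/5 %,
  ≈ 1.5 sessions per subject, so 60 subjects give the ~90-session cohorts
  used in tests and the acceptance script);
* per-session scores from truncated normals whose *post-truncation* mean
  and SD are fitted to the class profiles (dementia MMSE 16.4 ± 4.8 on
  [0, 23], non-dementia 28.6 ± 1.8 on [24, 30], analogous profiles for age,
  LM II and letter counts). Non-dementia LM II is a mixture of MCI
  (forced at/below the cutoff) and controls (forced above); the control
  mean and variance are solved from the mixture identities so the class
  moments still match. Where a hard rule range caps a variance (dementia
  LM II on [0, cutoff], the MMSE bands), the mean is matched and the SD is
  structurally compressed — the tests assert SDs only for the unconstrained
  scores (age, letters);
* transcripts from a Markov chain over a six-tag POS grammar with
  Zipf-weighted vocabularies. The separation parameter δ enters through
  λ = δ/(1+δ), which interpolates the transition matrix (dementia: more
  fillers, earlier sentence ends; non-dementia: longer content chains), the
  Zipf exponent (dementia: lower vocabulary richness) and the probability
  (0.45·λ) of drawing from a class-exclusive subvocabulary. At δ = 0 the
  classes are token-identical by construction; the default δ = 4 (λ = 0.8)
  produces a strongly separable cohort. Tokens are written as `word/TAG`,
  so the default tokenizer recovers the tag stream and the letter counts
  include the tag suffixes — self-consistent within the synthetic dialect;
* atypical sessions (default 25 %, matching the 108/432 test-only fraction)
  receive score patterns that fail the training criteria — alternating
  between non-typical rule patterns and fallback patterns with a matching
  clinical diagnosis; excluded sessions (default 27 %, matching the 158/590
  screened-out fraction) rotate through the four exclusion triggers.
  Education defaults to {9, 12, 16} years with mode 12, solely to exercise
  all cutoff branches.

What passing tests on this generator shows: the plumbing, the leakage
protection, the stratification, the vote arithmetic and the monotone
response of accuracy to class separation. What it does not show: that real
dementia speech is separable — the generator's class signal is planted, its
"morphemes" are synthetic syllable strings, and its within-class
heterogeneity is far milder than clinical reality. Published real-data
accuracies are therefore out of reach by design, and the package makes no
claim about them.

## Numerical conventions and degenerate inputs

* Embedding initialization: uniform in (−0.5, 0.5)/dim; output matrices
  start at zero; sigmoid inputs clipped at ±6 (lookup-free word2vec
  convention); learning rate floors at 1e-4 of its initial value.
* Vote ties: `select_vote_threshold` returns the smallest maximizing
  threshold.
* AUC ties: midranks (exact 1/2 per tied pair); single-class AUC is an
  error, not NaN.
* χ² requires positive margins; O = E tables clamp to exactly 0.
* Classifier scores are clipped into [0, 1] and asserted finite; empty
  prediction input returns an empty vector; feature-width mismatches are
  errors.
* Metrics reports assert the exact identity
  `accuracy = (sens · P + spec · N) / (P + N)` on every construction.
* The worked fixture is fully hand-constructed (fixed per-session text
  seeds) and regenerates byte-identically; it ships as a labeled
  `_synthetic` CSV under `inst/extdata/`.

## Problem sizes

The test suite and acceptance script run end-to-end pipelines at 60
subjects / ~90 sessions with 10-model voting (900 fits per run, Gaussian
naive Bayes as the default family for the property checks, the network
exercised on smaller slices), an embedding corpus of ~35 k tokens, and
moment checks at ~500 sessions. These sizes were chosen so a full check of
every invariant — including two complete LOOCV runs at δ ∈ {0, 4} —
completes in a few minutes on one core while keeping every statistical
tolerance meaningful (binomial bounds at n ≈ 90 are ±0.10).

## Known limitations

* The embedding modes bracket, but do not reproduce, the proprietary
  vectorization they replace; no pretrained contextual vectors ship with
  the package (a fixed-width external vectorizer can be plugged in).
* Threshold selection on pooled held-out votes is optimistic; use a
  pre-registered threshold for unbiased reporting.
* The network's hyperparameter defaults are not tuned per dataset; the
  bundled randomized search is deliberately small.
* Ternary classification (dementia / MCI / control) is not attempted; MCI
  is folded into non-dementia by the labeling rules.
* The generator does not model education–score correlations, realistic
  Japanese morphology, or acoustic phenomena.
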