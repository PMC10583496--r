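---
title: "Lexical speech features and their test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical speech features and their test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechlex)
library(dplyr)
```

## The problem

Lexical-semantic properties of spontaneous speech — how many words a person
produces, how rich their vocabulary is, how often they hesitate or fall back
on semantically empty nouns — are candidate digital biomarkers for early
cognitive decline. Before such features can track an individual's cognitive
status over time, they must behave like *traits*: a short speech sample has
to be consistent with other samples from the same person. speechlex
implements the psychometric side of that question for a protocol of five
speech elicitation tasks per participant: two expository prompts (describe an
important person, ET1; a meaningful place, ET2) and three picture
descriptions (PDT1–PDT3, e.g. the Cookie Theft scene), in a cohort of older
adults with and without mild cognitive impairment (MCI).

## The sixteen features

Each transcript is reduced to sixteen features (`speech_feature_names()`):

* **word_count** — number of lexical word tokens N. Fillers count as words;
  partial (abandoned) words and nonword vocalizations do not.
* **Nine proportion features**, each 100 × count / N: fillers (um, uh, …)
  and empty words (thing, stuff, …) by lexicon membership; definite article
  *the*; indefinite articles *a*/*an*; pronouns (Penn Treebank tags PRP,
  PRP\$, WP, WP\$); nouns (NN\*); verbs (VB\*); determiners (DT, PDT, WDT);
  and content words (surfaces not in the stop-word list). The per-100-words
  scale is a readability choice; the counts themselves are what carry
  information, and correlations are scale-invariant, so none of the
  reliability results depend on it.
* **frequency** — token-weighted mean of log10 per-million word frequency,
  with a floor for out-of-vocabulary words. Higher = more common words.
* **type_token_ratio** — V/N for V distinct word types.
* **honore_statistic** — R = 100·ln N / (1 − V1/V), where V1 counts hapax
  legomena. Undefined when V1 = V (every type spoken once); the package
  returns NaN with a warning there rather than inventing a value.
* **brunet_index** — W = N^(V^−0.165); lower = richer vocabulary. Spontaneous
  speech typically lands between 10 and 15.
* **speech_rate** — *all* produced tokens (words, partial words, nonwords)
  per second of elapsed speaking time; the only feature where partials and
  nonwords participate.
* **filler_rate** — filler tokens per second.

The Honoré and Brunet formulas are the standard literature forms. Published
per-task Honoré summaries in this literature are sometimes reported on a
rescaled axis (single digits rather than the hundreds the canonical formula
produces); speechlex deliberately keeps the canonical form and makes no
attempt to reverse-engineer any particular rescaling.

Part-of-speech tagging is an injected dependency: any function mapping a
vector of word surfaces to equal-length Penn Treebank tags satisfies the
contract. The bundled `baseline_tagger()` (closed-class lookup plus suffix
heuristics) lets a corpus run end to end without an external NLP stack, but
it is a baseline, not a research-grade tagger; synthetic corpora carry gold
tags precisely so that no statistical result in this package depends on
tagger accuracy.

## Transcript dialect and cohort rules

Transcripts are plain UTF-8 text, whitespace-tokenized and lowercased, with
two annotation markers: a trailing `-` flags a partial word and a `&` prefix
flags a nonword vocalization. Fillers are ordinary words, recognized by
lexicon. Participants missing any transcript or any positive per-task
duration are excluded entirely (complete-case rule), so every admitted
participant contributes exactly 5 × 16 feature values.

MCI status is operationalized from normed neuropsychological T-scores
(population mean 50, SD 10): at least two tests at or below T = 40 — one SD
below the mean, boundary inclusive — *within the same cognitive domain*.
The stricter same-domain form is the default because it is the operative
clinical criterion; the looser variant (any two low tests, regardless of
domain) is available via `require_same_domain = FALSE`, since both readings
circulate and a reanalysis may need either.

## The reliability model

Raw features live on wildly different scales, so values are z-scored within
every (feature, task, group) stratum using the sample (n − 1) SD. Z-scoring
is affine within a stratum, so within-group correlations are identical
before and after; full-sample correlations computed on group-stratified
z-scores differ slightly from raw-value correlations because each group is
centred separately — this matches the analysis the package reproduces.

**Within-task-type reliability.** For each feature, Pearson correlations are
computed between repeated instances of the same task type: one ET1–ET2
correlation, or three pairwise picture-task correlations. Correlations are
averaged after the Fisher z transform (atanh), then back-transformed:
r̄ = tanh(mean atanh r). Fisher averaging is variance-stabilizing and exact
for identical inputs.

**Resampling null.** Whether the observed mean correlation exceeds what any
two measurements of the same feature would share, absent within-person
consistency, is judged against a resampling null: in each of (by default)
10,000 replicates, participants on one side of every task pair are re-paired
by a uniformly random *derangement* — no participant is ever paired with
themself, and each participant's values are used exactly once. One
derangement serves all sixteen features within a replicate, preserving the
cross-feature dependence structure; the alternative (an independent
permutation per feature) would destroy it and narrow the null. All
per-feature correlations are recomputed and Fisher-averaged over features
and pairs into one null value per replicate. The one-sided p-value uses
add-one smoothing, (1 + #{null ≥ observed}) / (1 + reps), because a finite
resampling distribution cannot support p = 0 and the scientific claim
("larger than chance pairing") is directional.

**Group comparison.** The sixteen per-feature mean correlations of the MCI
and intact groups are compared with a two-sample pooled-variance t-test on
the Fisher-z scale (variance-stabilized), giving 16 + 16 − 2 = 30 degrees of
freedom; the confidence interval is back-transformed to the r scale.
Pooled rather than Welch variance is used because the design is a fixed
16-per-group comparison and the integer df is part of the reported shape.

**Intraindividual variability (ITV).** For each feature, each participant's
sample SD across their five z-scores is averaged over the group
(`mode = "per_participant_sd"`, the default). A second mode
(`"variance_pooled"`) computes the sum of squared per-task SDs divided by
the number of participants; it exists because the two published descriptions
of this index (prose vs printed formula) disagree, and the package exposes
both rather than silently picking one. The default follows the prose
description. Sample (n − 1) SDs are used throughout.

## The synthetic cohort generators

No transcript corpus of this kind is publicly deposited, so the package
validates its machinery on synthetic cohorts at two levels.

**Feature level** (`generate_feature_matrix()`): participant i's trait for
feature f is θ ~ Normal(μ, √ρ_f) and each task observation adds independent
Normal(0, √(1 − ρ_f)) noise, so the population inter-task correlation is
exactly ρ_f with unit marginal variance. The default ρ profile spans
0.245–0.87 across the sixteen features, emulating the spread of observed
picture-task reliabilities (strong: word count, content words, speech rate;
weak: Honoré statistic, empty words). Group sizes default to 10 MCI + 29
intact. Expository tasks receive a +0.5 z offset, standing in for their
systematically longer productions; the offset is absorbed by per-task
z-scoring and does not affect correlations.

**Transcript level** (`generate_transcripts()`): each participant draws a
stable speaking profile — verbosity (lognormal around 250 words for picture
tasks, ×2.5 for expository), filler propensity (logit-normal around ~1 per
100 words), empty-word substitution rate, per-person Zipf exponent
(1.1 ± 0.08) over a ranked vocabulary with closed-class words at the top
ranks, and base speech rate (2.3 ± 0.35 words/s) — and produces five
transcripts with Poisson word counts, Bernoulli filler insertion,
noun→empty-word substitution, ~1% partial words, ~0.5% nonwords, and
durations derived from the speech rate with 5% lognormal noise. Gold tags
accompany every word token, and T-scores consistent with each participant's
group are drawn for a 13-test battery across five cognitive domains so the
classification rule can be exercised end to end. Person-level variance in a
propensity is precisely what makes the corresponding feature reliable, which
gives the generator its validation role: shrink a propensity's person-level
spread to near zero and that feature's reliability collapses toward the
null, while features with wide person-level spread stay high.

What the generator does *not* emulate: discourse structure, syntax, semantic
content of the pictures, disfluency clustering, or any acoustic property.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated — not that real elderly speech has any particular
reliability. All generators are pure functions of (spec, seed) and restore
the caller's RNG state.

## Numerical choices and edge cases

* Degenerate inputs fail loudly: empty transcripts, nonpositive durations,
  untagged word tokens, constant z-scoring strata, and zero-variance
  correlation columns are errors (the latter two carry a distinct condition
  class that the CLI maps to exit code 3).
* Honoré with V1 = V returns NaN with a warning (division by zero).
* Derangements are drawn by rejection sampling from uniform permutations,
  which is exact (acceptance probability ≈ 1/e) and unbiased.
* Feature files round-trip at full precision: doubles are written in
  shortest round-trip representation and re-parsed via `strtod`.
* Correlations are computed on column-standardized matrices as cross
  products over (n − 1), which is numerically identical to `cor()` and lets
  each resampling replicate reuse the standardized matrices.

## Problem sizes used in the test suite

The suite validates oracle equivalence on 1,000 random transcripts,
null calibration on 500 simulated reliability-free cohorts of n = 29 with
500 replicates each (one-sided rejection at α = .05 lands near the nominal
rate), ρ recovery at n = 500 for ρ ∈ {0.3, 0.6, 0.9}, a 10,000-replicate
null on a ρ = 0.6, n = 100 cohort, and a full transcript-level pipeline run
at the default 39-participant scale. These sizes give stable Monte-Carlo
behaviour while keeping a full test run in a few minutes.

## A worked run

```{r example}
spec <- cohort_spec(seed = 20)
corpus <- generate_transcripts(spec)
features <- extract_corpus_features(corpus, corpus$lexicons)
rel <- reliability_analysis(features, reps = 1000, seed = 21)
glance(rel)
```

```{r plots, fig.width = 7, fig.height = 5}
autoplot(rel)
```

## Known limitations

* The bundled stop-word, filler and empty-word lists are documented defaults,
  not a claim about any specific study's lexicons; substitute project lists
  via `lexicon_resources()`.
* `baseline_tagger()` is heuristic; part-of-speech proportion features on
  real transcripts should use a trained tagger through the tagger contract.
* The bundled frequency fixture (`inst/extdata/frequency_demo.tsv`) covers
  only very common words with order-of-magnitude per-million values; real
  analyses should supply a frequency table from a large reference corpus.
* Reliability is studied cross-sectionally over one session's five tasks;
  nothing here addresses stability over weeks or months.
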