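---
title: "Multilingual speech markers of AD: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilingual speech markers of AD: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechmarkers)
```

## The problem

Alzheimer's dementia (AD) impairs language early — most prominently
semantics — and spontaneous speech elicited by the Cookie Theft picture
description is a standard clinical window onto that impairment.  Features
computed automatically from such descriptions discriminate AD from healthy
controls (HC) well, but a feature that discriminates within one corpus in
one language is not, by itself, evidence of a *cognitive* language
impairment: it may encode task strategy, recording conditions, or the
language itself.  This package operationalizes a replication-based remedy:
extract the same feature families from an English and a French cohort,
keep the features that are statistically significant in *both* languages
(excluding task-specific scores by construction), and compare classifiers
trained on "all" versus "generalizable" feature sets under leave-one-out
cross-validation (LOOCV) with the error decomposed by language.

The clinical corpora this design targets are access-restricted, so the
package ships a synthetic bilingual cohort generator with known planted
effects; every pipeline stage is tested against that ground truth.

## Feature families

**Task-specific (89 features).** Sixteen information units (IUs) — boy,
girl, woman, kitchen, exterior, cookie, jar, stool, sink, plate,
dishcloth, water, window, cupboard, dish, curtain — each expandable to
synonymous keywords ("boy" may be said as *brother* or *son*).  Per IU:
mentioned (0/1), mention count, and share of all mentions.  Spatially, the
picture is divided three ways (halves, quadrants, vertical stripes); per
region we report keyword tokens, keyword type–token ratio,
keyword-to-word ratio and the fraction of the region's IUs covered, plus
the number of left/right switches along the mention sequence.  These
features measure task performance, not language, and are therefore
*excluded* from the generalizable set by definition.

**Semantic (25).**  Global IU summaries (unique IUs, unique and total
keywords, densities per word, keyword-to-non-keyword ratio, fraction of
the 16 IUs covered, keyword TTR, per-second IU efficiencies), word
frequency and word length statistics over all words and over mentioned
keywords, the type–token ratio, and the moving-average TTR (MATTR,
window 10 words) which reduces the length dependence of lexical
diversity.

Two definitional points are worth making explicit.  First, the reference
description of these features lists two distinct quantities under one
name ("unique IU efficiency": unique keywords per word, and unique IUs
per second); the registry requires unique names, so the word-count
version is registered as `unique_keyword_density` and the duration
version keeps the efficiency name.  Second, "number of total IUs" and
"number of total keywords" are treated as the same quantity — the worked
example forces that reading.

**Syntactic (44).**  Sentence counts and mean sentence length, dependency
length statistics (mean/median/max of the absolute token distance from
each non-root token to its head), per-tag counts and ratios over the
17-tag universal POS inventory, and noun/verb, pronoun/noun,
determiner/noun and open/closed class ratios.  POS ratio denominators
exclude punctuation, except `PUNCT_ratio` which is relative to all tokens
(otherwise it would be 0/undefined by construction).

**Paralinguistic (209).**  Computed from the waveform after resampling to
16 kHz mono: (i) temporal features from intensity-based syllable nuclei
(peaks at least 2 dB above the preceding dip, above a silence threshold
of −25 dB relative to the intensity maximum; pauses are silent gaps of at
least 0.3 s) — syllable count, speech and articulation rate, speaking
ratio, and a pronunciation score defined as the share of nuclei falling
in voiced frames (the cited tool's "posteriori probability score" is
proprietary to it; this voiced-nuclei fraction is our documented
stand-in); (ii) six F0 statistics from an autocorrelation tracker
(75–500 Hz search band, voicing threshold 0.45 on the normalized
autocorrelation peak, parabolic lag interpolation); (iii) 168 MFCC
summaries — 14 cepstral coefficients (the first is the static energy
term) × {static, velocity, acceleration} × {mean, variance, skewness,
excess kurtosis}, with frame differences as velocity and differences of
differences as acceleration; (iv) 28 spectral summaries — RMS, centroid,
bandwidth, flatness, zero-crossing rate, normalized loudness and flux,
each summarized by mean/max/min/sd.  Frames are 25 ms at a 10 ms step
(40 ms for F0, which must span two periods at the 75 Hz floor).
Skewness and kurtosis of zero-variance series are defined as 0 so that
constant channels do not propagate NaN into the classifiers.

The implemented family sizes (89/25/44/209, total 367) are what the
registry reports; `feature_registry()` is the single source of truth.

## Ingestion choices

CHAT transcripts are reduced to the participant tier only; examiner
prompts describe the examiner, not the patient.  Markup stripping is
deterministic: timing bullets, event codes and all bracketed annotation
groups (including retracing/repetition markers) are removed while the
repeated words themselves are kept; shortenings like `(be)cause` are
expanded; unintelligible placeholders (`xxx`) are dropped.  Fillers
("uh", "um", "euh") count as words by default.  Keyword matching is
case-insensitive on surface forms with a small rule-based plural
inflector (no model download); multi-word keywords match longest-first
without overlaps, so *cookie jar* is one jar mention, never an extra
cookie.  POS tagging sits behind a backend contract; the builtin backend
is a deterministic closed-class lexicon plus suffix tagger with a fixed
head-assignment scheme (root = first verb; determiners/adjectives/
adpositions attach to the next noun; everything else to the root).  It is
not a parser of general English or French — it is exact on the synthetic
templates and reasonable on picture-description vocabulary, and a
pretrained tagger can be plugged in via the `tagger` argument.  The
packaged word-frequency tables are hand-curated synthetic approximations
of large-corpus relative frequencies covering the task vocabulary;
out-of-vocabulary words look up as 0.

## Screening and selection

Per feature and per language we report HC/AD means, a tie-corrected
Kruskal–Wallis H (χ², df = 1 for two groups), the raw p, a Bonferroni
adjusted p, and the point-biserial correlation with the group indicator
(AD = 1) as a cross-language comparable effect size.  The Bonferroni
multiplier defaults to the runtime registry size (367 here), with an
override for users who want to mirror an external feature count.
Correction is applied within each language independently (each feature
has four significance values).  Selection uses the *uncorrected* p with
strict inequality p < 0.05 in both languages: requiring replication in
two independent cohorts is itself the filter, and a Bonferroni-first rule
would make the set depend on the registry size.  Missing values are
dropped per feature (pairwise deletion), maximizing usable data.

## Classification protocol

LOOCV throughout.  Within each fold, missing values are imputed with
training-fold medians and features standardized to training-fold
mean 0 / sd 1 — the held-out subject never contributes to either
statistic (asserted by a poisoned-held-out-value test).  Imputation and
scaling are engineering additions (the SVM and MLP are scale-sensitive)
and are applied identically in every run.  Models: ridge-penalized
logistic regression at the fixed penalty equivalent to inverse strength
C = 1; an RBF-kernel SVM at cost 1; and a one-hidden-layer perceptron
with 100 logistic units and weight decay 0.01, other settings at the
fitters' defaults (the MLP's iteration cap is the fitter's default 100,
seeded per fold for reproducibility).  The AUC is computed once from the
pooled held-out scores — with one test sample per fold a per-fold AUC is
undefined, so "average across iterations" can only mean the pooled
rank-based estimate.  Hard predictions use each model's native threshold
(0 for margin scores, 0.5 for probabilities).  By default features are
selected once on the full data before LOOCV, reproducing the published
protocol (which leaks selection information); a nested mode re-selecting
inside each training fold is the honest alternative and is planned as the
`mode = "nested-selection"` configuration.

The scenario grid is {English, French, multilingual} × {all language
features, generalizable features}, plus an English baseline over all
subgroups including task-specific features, and a multilingual age-only
baseline — eight scenarios per model.  Multilingual runs concatenate the
cohorts; the language tag is kept only to decompose errors (per-language
confusion matrices always sum cell-wise to the overall matrix), never as
a model input.

## The synthetic cohort

The generator emulates the statistical structure the design needs, not
natural discourse.  Per subject, each IU is mentioned with a
group-dependent probability (HC 0.7, AD 0.4), realized 1 + Binomial(3,
0.4) times as a templated sentence ("the *keyword* *verb phrase*" / "le
*keyword* ..."); with group-dependent probability the subject uses a
specific synonym over the IU head noun (HC 0.5, AD 0.2); repeated
mentions are replaced by a pronoun with group-dependent probability (HC
0.1, AD 0.35); fillers are inserted at a group-dependent rate (HC 0.1,
AD 0.4 per sentence).  Durations are log-normal (medians 65 s HC, 50 s
AD, σ = 0.45, consistent with reported recording lengths of roughly one
minute); ages are normal with the published cohort means and SDs (English
66.1/66.8, French 75.4/81.6) — so the French AD group is deliberately
older, letting the age-only baseline probe that confound.  Verb-phrase
templates contain no IU keywords and, in French, no pronouns, so the
planted effects are not diluted by template vocabulary.

Paralinguistic rows are sampled from language-offset Gaussians rather
than synthesized audio (tests of the acoustic extractors use tone and
burst generators instead).  Planted standardized shifts: bilingual —
`ratio_speaking` −0.8, `speech_rate` −0.8, `normalized_loudness_std`
−0.8 (|d| = 0.8 is the size at which replication in both cohorts is
reliable at n = 50/group); French-only — `energy_skewness` +0.9,
`mfcc1_skewness` +0.8, `f0_q25` −0.8; English-only — `bandwidth_mean`
+0.6, `mfcc4_kurtosis` +0.6.  The declared ground truth lists every
feature the generator perturbs with a predictable sign.  `keyword_TTR`
is deliberately *not* declared: the AD group's generic-keyword
repetition lowers it while pronoun substitution removes exactly those
repeated keywords and raises it back, so the generator plants no
reliably signed effect on it.

What passing tests on this cohort do **not** show: robustness to real
disfluent speech, ASR errors, diarization failures, real acoustic
channels, or real syntactic variety.  The generator validates the
statistical machinery, not the clinical claim.

## Numerical choices and degenerate inputs

Ratios with zero denominators are missing (`NA`), with warnings where
the condition is informative (all words are keywords; constant feature
in a fold; no dependency arcs).  All-silent audio yields zero syllables
and a missing articulation rate; unvoiced audio yields missing F0
statistics.  Constant features are dropped per training fold.  The AUC
uses midranks (ties count 1/2).  Resampling is linear interpolation —
adequate for the narrowband measures used here; pre-filter externally if
strong energy lives above the new Nyquist.  All randomness flows from a
single integer seed; fixed seed means byte-identical cohorts, fits and
reports.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
assertions sharp while keeping a full run comfortably interactive:
type-I calibration on 1000 null features at n = 50/group/language
(tolerance: the 95% binomial interval half-width at 1000 tests);
selection recovery over 100 generator seeds at n = 50/group/language;
classification sanity at n = 20/group/language with 20 label
permutations; oracle equivalences on 100 random instances each (the MFCC
oracle is an independent numpy/scipy implementation of the same standard
definition, compared at 1e-6); structural checks of the 24-run grid at
n = 8/group/language on a compact feature table.

## Known limitations

No diarization: if examiner speech is present in the audio it enters
the paralinguistic features.  No %mor tier parsing, no ASR.  The builtin
tagger is deliberately minimal; syntactic features computed on free text
with it should be interpreted with care (plug in a pretrained tagger for
real data).  The published per-corpus statistics and AUCs require the
restricted corpora and are out of scope; the package reproduces the
worked example and summary statistics exactly, and everything else by
property.
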