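---
title: "Methods: speech features, group contrasts, and outcome prediction in uhrspeech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech features, group contrasts, and outcome prediction in uhrspeech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uhrspeech` analyzes short (45 s) timed speech recordings from ultra-high-risk
(UHR) psychosis cohorts with three clinical outcomes — conversion to
psychosis, remission, maintained UHR status. This vignette documents the
models and procedures the package implements, the tunable parameters and
their defaults, what the synthetic cohort generator does and does not
emulate, and the design decisions taken where several reasonable choices
existed.

## Linguistic features

All four linguistic features read only the timed transcript (ordered word
tokens with start/end times in seconds; closed–open intervals `[start, end)`
compared at 1 ms resolution).

* **WPM.** On a fixed 45 s task, words per minute is defined as
  `word count × 0.75`. We keep this literal definition as the default even
  though dimensional words-per-minute on a 45 s task would divide by 0.75
  rather than multiply: the feature is z-standardized before every analysis,
  so the constant rescaling cannot affect inference, and keeping the stated
  form makes effect sizes directly comparable. A dimensional mode
  (`word_count / (duration/60)`) is available via `compute_wpm(mode =
  "per_minute")`, and the mode used is recorded in the output metadata.
* **Articulation rate.** Word count divided by speaking time (the summed
  token durations, pauses excluded), in words/s.
* **Dysfluency.** `(short pauses + medium pauses + interjections) / word
  count`. Pause classes are short (< 0.3 s), medium (0.3–0.7 s), long
  (≥ 0.7 s); long pauses are excluded from the numerator. The class
  boundaries are left-closed and right-open (`[0.3, 0.7)` is medium): the
  verbal definitions are ambiguous exactly at 0.3 and 0.7 s, so we fixed one
  convention and test it explicitly. Interjections are detected by a
  part-of-speech tagger when one is supplied (any function mapping tokens to
  tags fulfils the contract); without a tagger, membership in a packaged
  filled-pause lexicon (um, uh, erm, ...) is used, case-insensitively.
  Interjection tokens count both as words (denominator) and as events
  (numerator), which bounds the ratio and avoids an arbitrary word/non-word
  split.
* **Sequential coherence.** Cosine similarities between embeddings of
  adjacent in-vocabulary words are smoothed with a centered moving average of
  window 5 (the window shrinks at the sequence edges), and SC is the mean of
  the smoothed sequence. Smoothing a sequence and then averaging equals plain
  averaging when the window treats edges symmetrically, so the choice of
  edge handling is what matters; shrinking windows keep every similarity in
  the statistic. We interpret the moving average as running over *similarity
  values* (not words); sequences shorter than the window reduce to the plain
  mean. Out-of-vocabulary tokens are skipped by default (`oov_policy =
  "skip"`), since any embedding table has finite coverage; an error policy is
  available.

Two consequences worth noting: SC is invariant to any global rotation of the
embedding table (cosines are preserved), and with the dimensional WPM mode a
pause-free transcript satisfies `WPM = 60 × AR` exactly. Both are enforced by
tests.

### Pause derivation

Silences between consecutive tokens become pauses only when they last at
least `min_gap_s` (default 0.05 s — well below the shortest analyzed class
boundary of 0.3 s, so no analyzed pause can be lost, while sub-50 ms gaps,
which are mostly segmentation noise, are ignored). Leading and trailing
silence is never a pause: dysfluency concerns within-speech pausing, and a
slow starter should not accrue pauses before speaking.

## Acoustic features

Acoustics are computed framewise: 40 ms Hann windows with a 10 ms hop for
both the pitch and intensity tracks (values logged in the run manifest).

* **F0.** Per-frame fundamental frequency by the peak of the normalized
  autocorrelation, searched over the sex-specific candidate band — 140–300 Hz
  for female speakers, 75–300 Hz for male speakers. We interpret the
  published high-pass/low-pass settings as the pitch floor and ceiling of the
  search band (standard practice in pitch analysis software), implemented as
  candidate-lag bounds rather than waveform filtering. The peak location is
  refined by parabolic interpolation, giving sub-sample period resolution
  (better than ±0.5 Hz at 150 Hz). A frame is voiced when its normalized
  peak reaches the voicing threshold (default 0.45, exposed in the API); a
  sub-octave guard additionally marks a frame unvoiced when half the best lag
  correlates almost as well (≥ 0.9 of the peak) and the implied frequency
  lies above the band ceiling — without it, a pure tone above the ceiling
  would be reported at half its true frequency. `F0_m`/`F0_sd` are the mean
  and sample SD over voiced frames only, and at least two voiced frames are
  required.
* **Intensity.** Per-frame `10·log10(mean square / P_ref)` with
  `P_ref = 4×10⁻¹⁰` (the square of the 2×10⁻⁵ reference pressure, treating
  samples as pressure-like), under normalized Hann weighting. With this
  reference a full-scale sine sits at ≈ 91 dB and the "omit below 10 dB"
  ambient-sound gate has an absolute meaning; for uncalibrated recordings
  absolute dB is arbitrary, so the gate threshold is configurable. `Int_m`/
  `Int_sd` are computed over frames at or above the gate.
* **HF500.** The ratio of summed power above 500 Hz to summed power at or
  below 500 Hz (DC excluded) in the long-term average spectrum of
  intensity-gated frames; silences are excluded because the gate removes
  them, which keeps the measure a property of the voice rather than the
  pause structure. Spectra use Hann-windowed frames zero-padded to at least
  1024 points. A recording with essentially no low-band energy (low-band
  fraction below 10⁻⁶ of total) is rejected as degenerate rather than
  returning a huge unstable ratio.

Gain behavior is pinned down by tests: F0 and HF500 are gain-invariant, and
mean intensity shifts by exactly `20·log10(g)` under gain `g`.

## Differential analysis

Each feature is z-standardized (mean 0, sample SD 1) and fit by OLS:

```
feature_z ~ DD + sex + BACS + BAI + outcome
```

with depression diagnosis (DD) binary, sex coded female = 0 / male = 1 (so an
expected lower male F0 appears as a negative coefficient), cognition (BACS)
and anxiety (BAI) as scalars, and the 3-level outcome dummy-coded with
**remitted** as the reference (all contrasts of interest are relative to
remission). Pairwise outcome contrasts (converted−remitted,
maintained−remitted, converted−maintained) are linear combinations of the
coefficients with covariance-propagated standard errors and t tests on the
residual degrees of freedom; they are invariant to the choice of reference
level. Missing covariates are handled by listwise deletion with a logged
count. Rank-deficient designs raise an error naming the aliased terms.

**FDR family.** Benjamini–Hochberg correction is applied, by default, across
the features of one family (4 linguistic or 5 acoustic) within each pairwise
contrast. With m = 4 this reproduces the kind of adjusted values the
contrast tables print (e.g. p = .001 → .004, p = .008 → ~.02); pooling across
contrasts or globally is available via `fdr_mode` since the family definition
is a genuine modeling choice.

**Cohort demographics.** Continuous covariates are compared by one-way
ANOVA — from raw values, or from per-group n/mean/SD summaries via the exact
algebraic identity (between-group and within-group sums of squares are
functions of the summaries alone), which the tests verify against raw-data
ANOVA. Categorical covariates use the Pearson chi-square test without
continuity correction.

## Outcome prediction

The 3-class outcome is reduced to two one-vs-all binary tasks:
converted-vs-all and remitted-vs-all. Models are linear SVMs (L2-regularized
hinge loss) with balanced class weights `w_i = N/(K·n_i)`, which equalize the
weighted class masses (`Σ w_i n_i = N`); weighting a class by an integer
factor is equivalent to replicating its samples, which the tests check
against the solver.

**Nested cross-validation.** The outer loop is leave-one-out; for each
held-out sample, an inner stratified 5-fold loop on the remaining n−1 samples
grid searches `C ∈ {0.001, 0.01, 0.1, 1, 10, 100}` (a symmetric log grid
around 1 — the published analysis tuned C but did not print its grid),
selecting the maximum inner balanced accuracy with ties broken toward the
smallest C (stronger regularization). The winner is refit on all n−1 samples
and predicts the hold-out. Feature standardization statistics are computed
inside each training split, never from held-out data; a corruption test
verifies that mangling a held-out sample cannot change its fold's selected C.
We standardize within folds even though a whole-cohort standardization
reading is defensible, because the leakage-safe variant is the conservative
one; a global mode exists for fidelity comparisons. If a class is too small
for 5 inner folds the fold count drops to the minority count (with a
warning); a minority class below 2 is an error. Inner-loop model selection
uses balanced accuracy (the evaluation metric; plain accuracy would favor the
majority class under imbalance). Stratified folds are assigned
deterministically (round-robin within class), so nested CV is reproducible
without consuming random state.

**Evaluation.** Balanced accuracy `BA = (TPR + TNR)/2` over the n outer-fold
predictions; predicting everyone into the majority class gives BA = 0.5 at
any imbalance. The 95% CI is a percentile bootstrap over 1000 resamples of
the fixed (truth, prediction) pairs — predictions are not refit under
resampling, the standard reading of a CI on held-out performance.
Single-class resamples are redrawn (capped, logged). A model is flagged
significant when the CI lower bound exceeds 0.5.

**Feature sets.** Five sets are evaluated per task: the four verbal rater
items (verbal expression, clear communication, fluency of speech, social
anxiety), the rater items en bloc, linguistic, acoustic, and
linguistic + acoustic. Item scores are averaged across the two raters before
modeling (a deliberate choice; modeling raters separately doubles the
dimensionality of an already small problem). The en-bloc set uses 15 of the
16 rated items by default — the source descriptions of the instrument
disagree on 15 vs 16 items for modeling, so the count is configuration
(`n_hisoc_items`), not code; the default drops the global
"overall impression" summary item, keeping the 15 specific items.

### Known operating characteristics

Two properties of this evaluation protocol deserve explicit mention.

* **The significance rule is mildly liberal at this scale.** With ~30–41
  held-out predictions, the percentile bootstrap under-covers and null BA is
  slightly optimistic (mean ≈ 0.52), so "CI lower bound > 0.5" fires on pure
  noise at roughly a 10% rate rather than the nominal 2.5%. The permutation
  null is nonetheless well behaved (mean BA within [0.45, 0.55] over 100
  replicates, enforced by a test). Flags on cohorts this small are screening
  evidence, not confirmatory inference.
* **One-vs-all tasks share their negatives.** A signal specific to one
  outcome group partially informs the other task: if a feature separates
  remitted from everyone else, the converted-vs-all learner can exploit
  "feature-high ⇒ negative", with a balanced-accuracy ceiling of
  `(1 + n_rem/(n_rem + n_maint))/2` (≈ 0.76 at 12/15/14). Significance on one
  task therefore does not localize the signal to that task's positive class.

## The synthetic cohort generator

The generator's defaults are the study conditions: 12/15/14 participants per
outcome group, a 45 s task, covariate marginals on the scale of the cohort's
demographic table (≈ 68% male, BAI mean ≈ 17 and SD ≈ 13 truncated at 0,
depression prevalence ≈ 27%, a scalar cognition score at ≈ 57 ± 12 — the
instrument has several subtests and the pipeline accepts any scalar cognition
column), and group effects matching the reported contrasts: converted
word count −1.17 SD and pause/interjection rates +1.39 SD relative to
remitted, maintained word count −0.79 SD, and no acoustic group effects
(consistent with the reported null acoustic findings). Where the source
material states no value we chose once what is realistic for conversational
speech — word count ≈ 110 ± 22 per 45 s (≈ 2.7 words/s), log-normal word
durations with median 0.25 s, a pause after a word with probability ≈ 0.25
drawn from a short/medium/long mixture (0.50/0.35/0.15) so every pause class
occurs, a 5% filled-pause rate, and sex-specific base F0 of 200 Hz (female) /
120 Hz (male) with 12 Hz between-speaker and 8 Hz within-utterance SD.

Audio is a harmonic source (summed harmonics under a configurable spectral
tilt, −9 dB/octave by default) following a smooth random F0 contour during
token intervals, with 5 ms raised-cosine edges, over a pink-noise floor
(default 0 dB, i.e. below the 10 dB intensity gate; the acoustic conditions
of real recordings — noise floor, clipping — are not documented anywhere we
could verify, so the floor is a parameter rather than an assumption). This
gives simultaneous, independently controllable ground truth for F0,
intensity, and HF500. Transcript text is sampled from a packaged 48-word
topic-clustered vocabulary via a cluster random walk, and embeddings for it
are built with controlled within-cluster cohesion and near-orthogonal
cluster centers, so SC has construction-level ground truth.

What the generator deliberately does **not** emulate: intelligible phonetic
content (no phonemes or formants — the audio is unintelligible by design),
correlations between covariates and speech beyond the injected group effects,
rater drift or item-specific bias beyond shared item noise, reverberation or
channel effects, and disfluency phenomena other than silent pauses and
filled-pause tokens (no repetitions or repairs). Passing tests therefore
demonstrate that the pipeline recovers known effects from clean,
well-modeled signals; they do not certify performance on noisy clinical
recordings, ASR transcripts, or uncalibrated microphones.

Determinism is strict: the same configuration and seed reproduce every
artifact bit-identically; one global seed fans out to per-stage seeds by
fixed offsets so stages are individually reproducible.

## Numerical choices and degenerate inputs

* Pitch frames shorter than the longest candidate period are rejected at
  configuration time; recordings shorter than two frames are errors.
* All-zero intensity frames are invalid (−∞ dB) rather than numeric noise.
* Constant feature vectors cannot be standardized (error), and all-constant
  feature matrices make the SVM degenerate — the model then predicts the
  class with the larger total weight instead of crashing.
* Bootstrap resamples that lose a class are redrawn with a capped retry
  count; an absent class in the truth vector is an irrecoverable error.
* WAV I/O is 16-bit PCM mono; round trips are exact to the quantization step
  (2⁻¹⁵). TextGrid I/O writes the long text format and reads both long and
  short formats; boundaries survive round trips to 1 ms.
* Ties in the inner C grid resolve toward the smallest C; fold assignment is
  deterministic; `which.max` ties in pause-mixture sampling cannot occur
  (continuous draws).

## Problem sizes used by the test suite

The packaged tests validate the statistical properties at sizes chosen to
make the suite comfortably reproducible on a laptop: parameter-recovery
regressions at n = 300, type-I calibration over 1000 simulated null fits,
BH step-up equivalence on 1000 random p-vectors, permutation-null nested CV
over 100 replicates at n = 30 with a 2-point C grid, sign recovery of the
injected word-count and dysfluency effects over 200 simulated cohorts of
n = 41 (12/15/14), and end-to-end pipeline runs on 12-participant cohorts
with 8 s recordings. The acceptance script runs the full pipeline at the
study conditions (41 participants, 45 s audio).

## Limitations

The package reproduces an analysis protocol, not a clinical instrument. The
feature definitions are faithful to their published verbal forms, including
the non-dimensional WPM; the FDR family, SC smoothing order, rater
aggregation, and item count are defensible choices among several the source
descriptions leave open, each exposed as configuration. Absolute intensity
(and hence the 10 dB gate) is only meaningful up to the recording chain's
calibration. And at n = 41, both the regression contrasts and the bootstrap
significance flags carry the small-sample caveats discussed above.
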