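---
title: "Methods: speech-based ON/OFF medication-state discrimination"
author: "speechstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech-based ON/OFF medication-state discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

People with Parkinson's disease on dopamine replacement therapy cycle
between an "ON" state (symptom relief) and an "OFF" state (reduced relief).
The clinical rating scales that track these fluctuations need a trained
rater, so an automatic, objective marker computable from a few seconds of
speech is attractive: hypokinetic dysarthria makes speech energy, tempo and
— through the embodied-cognition link between the motor system and action
language — even word choice sensitive to dopaminergic state.

`speechstate` implements a complete within-subject pipeline for this
problem: three families of speech features, paired group statistics, and
subject-paired difference classification under repeated subject-wise
cross-validation. Because clinical audio of this kind is generally not
shareable, the package also ships a synthetic paired-cohort generator with
controllable state effects; every synthetic recording carries its
generation ground truth, so each pipeline stage can be tested as a
parameter-recovery problem.

# Feature extraction

All three speech tasks (picture description, reverse counting,
diadochokinetic "pa-ta-ka") produce a mono recording per subject and state;
the picture task additionally has a POS-annotated transcript.

## Acoustic features (130)

Thirteen mel-frequency cepstral coefficients are computed on pause-free
audio with a 25 ms window and 10 ms step: pre-emphasis (0.97), Hamming
window, power spectrum (FFT size = next power of two above the window), 26
triangular mel filters up to Nyquist, log, orthonormal DCT-II. The first
coefficient is replaced by the natural log of the total frame energy so
overall loudness is analyzed alongside spectral shape. Each of the 13
per-frame coefficient distributions is summarized by 10 descriptors — mean,
variance, kurtosis, skewness, mode, percentiles 10/25/50/75/90 — giving
exactly 130 features named like `MFCC #11 (pct75)`.

Pauses are defined on the intensity contour (32 ms frames, 10 ms step,
level in dB *relative to the recording's loudest frame*) as maximal runs
below −25 dB spanning at least 100 ms. An absolute dB threshold would be
meaningless without a calibration reference, and the relative reference
makes every detector gain-invariant; the 32 ms frame guarantees a 100 ms
pause spans at least seven frames.

## Prosodic features (16)

Syllable nuclei are detected as intensity-contour peaks above the −25 dB
silence threshold whose rise over the following dip is at least 2 dB (the
cited nuclei method's default dip; exposed as `minDipDb`). No voicing/pitch
gate is applied — a documented deviation knob that keeps the module
dependency-light. The inter-nucleus interval distribution is summarized by
8 descriptors (pct10, pct90, mode, mean, variance, skewness, kurtosis, IQR)
in two variants: raw intervals (`NS`) and intervals with spanned pause time
subtracted (`NSnp`, gaps floored at one frame step). The text describing
the original descriptor set does not say unambiguously whether both
variants were summarized; computing both (16 features) retains strictly
more information and `NS` is taken as the default prefix.

## Semantic features (61)

For the picture task, content words (nouns and verbs, duplicates kept, no
lemmatization, lowercased lookup) are compared by cosine similarity to ten
seed words — five action concepts (*action, act, move, play, energetic*)
and five non-action concepts (*inaction, sleep, rest, sit, wait*). Cosine
is used because the similarity only needs "larger = more similar" and it is
the standard word-vector similarity. Per seed, the similarity distribution
over the participant's words (pooled across word types) is summarized by 6
descriptors (median, pct10, pct90, skewness, kurtosis, IQR); one extra
feature `nw` counts *all* transcript tokens. Out-of-vocabulary words are
skipped and affect only `nw`. POS tags are an input contract; the package
tags its own synthetic transcripts with a dictionary tagger rather than
bundling a parser.

## Shared descriptor conventions

Percentiles use linear interpolation (type 7). Skewness and kurtosis are
Fisher moment definitions without small-sample correction, kurtosis is
excess, and both are defined as 0 for zero-variance samples. The mode is
the midpoint of the most populated histogram bin under the
Freedman–Diaconis width (capped at 4096 bins; median fallback for a
degenerate IQR). These conventions are implemented once and used by all
three families, and each is checked against naive brute-force oracles in
the test suite.

# Group statistics

Each feature is tested with a two-sided **paired** t-test on the
within-subject differences d = ON − OFF (a positive t means greater mean in
ON). The source description oscillates between "two-sample" and "paired"
phrasing; paired is the only defensible choice for a within-subject design
and is what the classification stage also uses. Significance is Bonferroni
at α = 0.05 over the task's full (non-degenerate) feature set by default;
the correction family is exposed (`correctionFamily`) because published
per-task tables are ambiguous about the family size. Features are ranked by
ascending p (ties: |t| descending, then name); zero-variance differences
are flagged degenerate and excluded from ranking.

Co-variation among the top-5 features is summarized per state by partial
correlations from the precision matrix: with P the inverse correlation
matrix, partial_ij = −P_ij / √(P_ii P_jj). A ridge argument covers
singular cases.

# Classification

For each subject the feature difference ON − OFF is one sample labelled +1
and its negation one sample labelled −1. Using both signed samples makes
the problem exactly balanced (chance = 0.5) and origin-symmetric; the
original description does not state whether one or both directions were
used, and the symmetric convention removes the arbitrary choice of sign.
Linear models are therefore fitted without intercept (a documented knob).

Evaluation is 10-fold cross-validation over *subjects* — both samples of a
subject stay on one side of every split — repeated over 50 independent
partitions, with accuracy pooled within a run and mean ± sd reported over
runs. Everything adaptive happens inside the training fold: column
standardization (mean 0, sd 1; training statistics applied to the test
fold), selection of the top-5 features by the paired t-test on training
subjects only, and hyperparameter tuning by an inner 5-fold subject-wise
CV (the "double-nested" layer). Four classifiers are compared: elastic net
(logistic loss, mixing {0.1, 0.5, 0.9} × penalty {0.01, 0.1, 1}),
L1-regularized logistic regression (penalty {0.01, 0.1, 1, 10}), Gaussian
naive Bayes (untuned), and a 200-tree random forest (max depth {2, 4,
unlimited}). The exact grids are not published; these are small,
conventional grids centered on the standardized-feature scale. Elastic net
and the L1 logistic model are fitted with `glmnet`, naive Bayes with
`e1071`, and the random forest with `ranger` (chosen for single-thread
speed inside the nested loop). Feature-set grids follow the per-task
combinations: picture uses NS, SF, NS+SF, MFCC, MFCC+NS, MFCC+SF,
MFCC+SF+NS; counting and diadochokinetic use NS, MFCC, MFCC+NS; `kSelected
= Inf` gives the all-features mode.

# The synthetic cohort generator

The generator emulates exactly the properties the features measure,
nothing more:

* **Utterances** are trains of raised-cosine-enveloped voiced bursts — a
  120 Hz pulse train through a single 500 Hz resonance plus a weak direct
  path that keeps harmonic energy up to Nyquist — over a continuous low
  "voicing floor" (≈ −18 dB re the burst peaks). The floor makes
  inter-burst gaps clear intensity dips for nucleus detection without
  registering as pauses; inserted pauses zero the envelope and are true
  silences. The burst count is `floor(rate × duration)` and all onsets,
  pauses and gains travel with the recording as ground truth.
* **State effects**: ON gets a high-band gain (band split at 8 kHz,
  defaults +3/−3 dB, i.e. a 6 dB ON−OFF difference), a lengthened upper
  tail of its inter-burst gaps (+0.1 s on a random 20 % of gaps), and a
  higher action-verb probability in transcripts (0.8 vs 0.2). These three
  directions mirror the positive-t findings the pipeline is designed to
  recover: more high-frequency energy, longer interval tails, and more
  action-word content in ON.
* **Subject and session variation**: per-subject baselines (rate factor,
  gain offset, verb-usage shift) plus per-recording jitters (0.75 dB gain,
  3 % rate, Poisson transcript length). Without the per-recording jitter
  the paired differences would be construction-deterministic and every
  t-statistic meaningless; with it, the strong-effect cohort lands at
  |t| ≈ 10–40 — strong but finite.
* **Toy embeddings** place action words around one anchor direction and
  non-action words antipodally, nouns isotropic, all unit-norm. The
  antipodal (rather than merely orthogonal) arrangement is what makes the
  *lower tail* (pct10) of action-seed similarity respond monotonically to
  the action-verb fraction: the bottom decile is occupied by non-action
  verbs, which become rare in ON transcripts.
* **Reproducibility**: every (subject, task, state) consumes its own RNG
  stream derived from the seed, so identical configs are bit-identical and
  adding subjects never perturbs existing ones.

What the generator does *not* emulate: phonetic content, speaker identity,
formant dynamics, dysarthric articulation beyond band-energy/tempo effects,
or natural language. Passing recovery tests therefore demonstrates that the
pipeline measures what it claims to measure and contains no leakage — not
that clinical effect sizes or the published clinical accuracies (which
require the non-public audio) are reproduced.

No quantitative physical effect sizes are published for any feature, so
the generator defaults are calibration choices fixed at design time: they
are the package's standing study conditions, not estimates of the clinical
effect.

# Problem sizes and numerical choices

The test suite and the acceptance script exercise the pipeline at sizes
chosen once as the package's standard study scale: a 25-subject
picture-task cohort at 44.1 kHz with 15 s of nominal speech per recording
(the diadochokinetic protocol is fixed at 10 s), the full picture
feature-set grid with all four classifiers at 10 CV repetitions for
recovery checks, 50 repetitions for the null-cohort chance-level check
(feature-level generator, 20 null features), 200 feature-level replicates
for the family-wise error simulation, and truncation to 10 s for the
duration-robustness comparison. Unit tests use 8–16 kHz cohorts of 2–5
subjects.

Numerical guards: log floors at ε = 1e−10 (intensity and MFCC energy);
pause-corrected gaps floored at one frame step; histogram mode capped at
4096 bins; zero-variance columns left at 0 during standardization with a
warning; degenerate t-tests flagged rather than dropped silently. The
chance-level check compares each classifier's mean accuracy to 0.5 within
two standard deviations of its 50 run-level accuracies; run-level
accuracies share one dataset, so this band reflects partition noise around
that dataset's own chance behaviour.

# Known limitations

* The generator's state effects are low-dimensional by design; real
  dysarthria affects many couplings (articulation, phonation, pitch) the
  generator leaves untouched.
* The −25 dB / 100 ms pause rule and the 2 dB nucleus dip are sensible
  defaults, not universally optimal; both are exposed as parameters.
* Published per-task significance tables cannot be reproduced numerically
  without the clinical audio; directional recovery on synthetic cohorts is
  the substitute implemented here.
* Transcripts are an input contract; no parser or speech recognizer is
  bundled.
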