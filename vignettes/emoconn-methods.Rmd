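---
title: "Decoding performed musical emotions from EEG: models and methods"
author: "EmoConn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding performed musical emotions from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

EmoConn is an offline decoding pipeline for a performed-emotion EEG
paradigm: a pianist plays a short excerpt neutrally for 30 s (the
baseline segment) and then plays a second page for 30 s while expressing
one of five target emotions — distressed, excited, depressed, relaxed or
neutral — which tile the two-dimensional valence–arousal affective space
plus its centre.  The analysis asks which EEG feature families
(band power, functional connectivity, effective connectivity) best
discriminate the expressed emotion, and whether the neutral baseline
helps or hurts feature selection.  This vignette explains the models,
the tunable parameters, the synthetic-data design and the numerical
choices; the README shows the code surface.

## Preprocessing

Scalp channels are re-referenced to the instantaneous mean of T7 and T8
and averaged into ten regions of interest (ROIs): mid-frontal left/right,
frontal left/right, centro-parietal left/right, parieto-occipital
left/right, fronto-central and central parieto-occipital.  A trial whose
baseline *or* emotional segment lacks an entire ROI is excluded; the log
records every exclusion, and the emotional and baseline tensors always
stay row-aligned.  Artifact rejection and independent-component cleanup
are assumed done upstream by the acquisition toolchain; EmoConn's
real-data entry point takes cleaned channel × sample matrices (or
plain-text TSV).

Each 30 s segment is filtered to 0.5–45 Hz and cut into eight
non-overlapping 3 s windows covering seconds 3 to 27 (half-open
intervals, 0-based window indexing), i.e. 1500 samples per window at the
500 Hz design rate.  The window axis is the spectral-averaging ensemble
for everything downstream.  Five sub-band versions are then produced —
delta 1–4, theta 4–8, alpha 8–12, beta 12–30 and gamma 30–45 Hz — giving
the per-band observation tensors (observations × ROIs × 8 × 1500).

**Filtering.** All filters are Hamming windowed-sinc FIR designs
(`signal::fir1`) applied forward–backward, so the effective response is
the squared magnitude and the net phase is exactly zero.  The
implementation multiplies the FFT of the reflection-padded signal by the
squared magnitude response, which is algebraically the forward–backward
convolution.  Tap counts give a ≤ 1 Hz transition (narrower near low
band edges: the transition is `min(1, low/2)` Hz).  The narrow
transition matters because squaring the response deepens the crossover
dip between adjacent bands; with it, the five sub-bands reconstruct the
1–45 Hz content of white noise with under 15 % relative RMS error.

## Feature families

**Band power** (100 features).  Per observation, ROI and band: absolute
power is the mean per-bin Hann-tapered periodogram power within the
band's range, averaged over the eight windows; relative power divides by
the mean per-bin 1–45 Hz power of the broadband windows.  A zero
denominator yields relative power 0, and an all-zero window yields power
0, never NaN.  Scaling a signal by $c$ scales absolute powers by $c^2$
and leaves relative powers unchanged.

**Magnitude-squared coherence** (45 features per band).  For ROIs $x,y$,

$$\gamma_{xy}(f) \;=\;
  \frac{\lvert\langle S_{xy}(f)\rangle\rvert^{2}}
       {\lvert\langle S_{xx}(f)\rangle\rvert\,
        \lvert\langle S_{yy}(f)\rangle\rvert},$$

where $\langle\cdot\rangle$ averages Hann-tapered periodogram spectra
over the eight windows (no sub-segmentation within a window).  Band
values are unweighted means of the per-bin $\gamma_{xy}(f)$ over bins
with $\text{low} \le f < \text{high}$; bins with a zero auto-spectrum
contribute 0.  The symmetric 10 × 10 matrix is vectorized as its upper
triangle in row-major order.  Two estimator facts the tests pin down: a
signal against itself gives exactly 1, and independent signals give
roughly $1/L = 1/8$, the classic positive bias of an $L$-segment
coherence estimator — zero coherence is *not* the null reference value.

**Binarized Granger causality** (100 features per band).  ROI $x$
Granger-causes ROI $y$ when adding $x$'s past to an autoregression of
$y$ on its own past reduces the prediction-error variance.  Per window,
two nested least-squares models are fitted without intercept (the
signals are zero-phase bandpass output, hence zero-mean): the restricted
model with $p$ own lags and the full model adding $p$ source lags; the
default order is $p = 5$, standard for short EEG windows and kept fixed
for speed.  The binary decision per ordered pair is averaged over the
eight windows, the diagonal is fixed at 0, and the full 10 × 10 matrix
is vectorized row-major (the diagonal columns are constant and die in
selection).

Two methodological gaps deserve care:

1. *The literal in-sample rule is degenerate.*  Comparing raw in-sample
   residual variances fires on nearly every pair, because added
   regressors almost never increase in-sample error.  The default rule
   therefore compares degrees-of-freedom-adjusted variances
   (RSS/(n − #coefficients)); a nested-model F-test at α = 0.05 and the
   literal raw rule are selectable alternatives.  On white noise the
   adjusted rule fires at P(F > 1) ≈ 0.42 and the raw rule at ≈ 1 —
   both rates are asserted in the tests.
2. *Band-limited windows carry far fewer degrees of freedom than
   samples.*  A 3 s window of a B-Hz-wide band sampled at 500 Hz has
   roughly $2BT$ effectively independent samples (e.g. ≈ 24 for alpha),
   not 1500.  With the literal count the adjusted rule and the F-test
   fire on *every* pair of independent band-filtered signals.  The
   per-band feature path therefore adjusts with the effective sample
   size $2 \times \text{bandwidth} \times 3\,\text{s}$ (floored at
   $2p+3$), which restores a ≈ 0.3–0.6 null rate in every band.
   `fitArPair` keeps the literal count by default so broadband/VAR use
   behaves classically.
3. *Zero-phase filtering erases directional traces.*  On band-filtered
   signals both directions of a planted lagged coupling tend to fire:
   the target's own lags already predict it almost perfectly and the
   misspecification dominates.  Direction is cleanly recoverable on the
   raw signals and on white-innovation VAR data (the tests do both);
   the band-filtered features should be read as *pair-level* coupling
   detectors.  This is a known caveat of Granger analysis after heavy
   filtering, inherited by any per-band GC design.

## Feature selection

Two regimes, applied per feature column:

* **Normalized** (baseline-aware): phase 1 runs a two-sample two-sided
  pooled-variance Student t-test of each condition's emotional rows
  against the aligned baseline rows, separately for the four non-neutral
  conditions, and keeps a feature only if p < 0.05 in **all four**
  (the "shared across conditions" intersection; neutral is skipped since
  neutral playing is not expected to differ from its baseline).  Phase 2
  then runs a one-way ANOVA across all five condition groups on the
  survivors and keeps p < 0.01.
* **Non-normalized**: phase 2 only.

No multiple-testing correction is applied in either regime — the
selection is deliberately the plain per-column screen, and its null
calibration (≈ 1 % retention at α = 0.01 over 10 000 null columns) is a
tested property.  "Normalized" here means *baseline-aware screening*;
no arithmetic baseline subtraction is performed (the `paired` and
baseline-subtraction variants exist as options but are off by default,
since the procedure is specified as a two-sample test).  Undefined
statistics (zero-variance columns) drop the feature and are logged.
All rows, including neutral, enter phase 2.  Row-wise vectorized t/F
statistics are used for speed and are unit-tested against
`stats::t.test` and `stats::aov`.

## Classification

One-against-one RBF-kernel SVMs (libsvm via e1071), which train
$\binom{k}{2}$ binary machines — 10 for the 5-class problem — and vote
with a deterministic first-maximum tie-break in class order.  Three
labelings: arousal (high = excited/distressed, low = relaxed/depressed,
neutral), valence (positive = excited/relaxed, negative =
distressed/depressed, neutral) and the 5-class emotion identity.

Evaluation is 5-fold cross-validation after a seeded global shuffle
(mixing participants, as in the study design); a leave-one-group-out
mode (`groupBy`, e.g. participant ids) is available as the stricter
subject-blocked alternative, and a stratified split helps small or
unbalanced inputs.  Per fold, columns are
standardized on training rows only; the RBF width defaults to
$\gamma = 1/(p_{\text{feat}} \cdot \operatorname{var}(X_{\text{train}}))$
and the cost to $C = 1$ — deterministic defaults rather than a tuned
grid, since the study protocol reports none.  Reports carry per-fold
train/test accuracies (mean ± sd) and pooled row-normalized confusion
matrices (rows = actual class, rows sum to 100 %).

## The synthetic cohort and its planted truth

The generator emulates the study design — 10 participants × 4 sessions ×
50 trials (2000 trials, 400 per condition), conditions blocked and
shuffled per session, 30 s baseline + 30 s emotional segment per trial
at 500 Hz over 10 ROIs — with three orthogonal families of planted
condition effects:

* **Band-power gains**: per condition × band × ROI amplitude
  multipliers.
* **Coherence couplings**: a shared band-limited latent source mixed
  into an ROI pair; the strength $s$ is the shared *variance fraction*,
  so the mix keeps unit variance and plants a band coherence of about
  $s^2$ while leaving band power untouched.
* **Directed couplings**: a lagged copy of the source ROI's
  pre-coupling signal mixed variance-preservingly into the target
  (feedforward, hence unconditionally stable; the companion-matrix
  spectral radius is still validated, and |coefficient| < 1 enforced).

Band-limited noise is made with the *same* zero-phase filters the
analysis uses, so generation and analysis bands agree exactly.  One
global seed expands into per-trial seeds via a counter scheme, and each
trial seed splits into baseline and emotional substreams, so any trial
or segment is individually reproducible.  `plantedTruth()` enumerates
every parameter that differs from the neutral/baseline set, and
`truthFeatureNames()` maps it onto feature-column names for recovery
studies.

The shipped preset (`defaultSyntheticSpec()`) was designed around three
constraints: every non-neutral condition must differ from baseline on
some features (so baseline-aware selection has survivors) — the common
graded coherence pairs and the ROI-9 alpha gains do this; each condition
must also have private signatures only the ANOVA-only regime can keep
(the condition-specific coherence pairs and directed edges), which is
what makes non-normalized selection the stronger regime; and the three
plant families live on disjoint ROI supports, because a lagged copy that
covaries with a shared source stops being variance-preserving and leaks
connectivity structure into band power.  The between-condition spread of
the power gains is deliberately small relative to the coherence spread,
reproducing the qualitative finding the pipeline is built to exhibit:
coherence features discriminate best, Granger features next, band power
worst, and baseline normalization reduces accuracy.

What the generator does **not** emulate: 1/f spectral shape (bands are
driven by white noise, so band power is proportional to bandwidth),
artifacts (blinks, EMG, electrode dropout), volume conduction or any
head geometry, non-stationarity within a segment, and the music itself.
Passing tests on this cohort therefore demonstrate the *pipeline's*
correctness and calibration — not that real performed-emotion EEG is
this separable; real-data accuracies will be far below the near-ceiling
synthetic ones.

## Numerical choices and degenerate inputs

* FFT lengths are padded to $2^a 3^b 5^c$ with $b \le 2$, $c \le 3$;
  radix-3-heavy lengths transform an order of magnitude slower in R.
* The all-pairs GC inner loop solves every nested model from one Gram
  matrix (`crossprod` of the lag blocks and targets) — residual sums of
  squares at the minimizer are quadratically insensitive to the solve's
  conditioning — and is asserted equal to the per-pair QR route.
* Ties: equal residual variances give GC 0 ("does not Granger-cause");
  SVM vote ties resolve to the first class in scheme order.
* Zero-variance columns: dropped and logged in selection; standardization
  maps them to 0 via a unit divisor in classification.
* Rank-deficient AR designs (constant source) are flagged and forced to
  GC 0.
* The coherence of a bin where either auto-spectrum is 0 is defined
  as 0; self-pairs evaluate to exactly 1.

## Problem sizes used by the shipped checks

The test-suite and acceptance script run, as the package's chosen study
sizes: the full 2000-trial schedule (metadata level); 100 segments per
condition (500 trials, emotional segments only) for the chance-level
cross-validation checks; 20 segments per condition with baselines for
the all-family accuracy-ordering comparison; 1000 replicates for the
coherence-bias oracle; 100 segments for VAR direction recovery; and
10 000 null columns / 50 replicates at n = 200 per condition for
selection calibration and planted-truth recovery.  Unit tests run a
100 Hz variant of the design (same band layout, gamma below Nyquist) to
keep filtering cheap.

## Known limitations

* Per-band binarized GC after zero-phase filtering is directionally
  blind (see above); interpret entries as coupling detectors.
* The default global shuffle mixes subjects across folds, so reported
  accuracies are optimistic relative to the leave-one-group-out mode —
  the default is faithful to the protocol being modelled, but worth
  remembering for real data.
* The effective-sample-size correction uses the flat $2BT$ rule; a
  taper-aware count would differ by a small constant factor.
* EDF ingestion is not built in; real data enters as channel × sample
  matrices or TSV plus a montage map.
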