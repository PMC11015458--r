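---
title: "Decoding color working memory from impulse-evoked EEG: models and methods"
author: "impulseWM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding color working memory from impulse-evoked EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impulseWM)
```

## The scientific problem

In a retro-cue working-memory task, a participant stores two colors, is cued
which one will be probed, and later reproduces the cued color on a color
wheel. During the memory delay a fixed, task-irrelevant high-contrast
stimulus (the *impulse* or "ping") is flashed. The EEG response evoked by the
impulse carries information about the hidden contents of working memory: a
multivariate decoder can read out which color is being held even when there
is no measurable sustained delay activity. This package implements the full
analysis chain for such experiments — decoding, representational similarity,
group statistics, and the behavioral bias analysis — together with a
generative simulator so that every stage can be exercised and tested without
recorded data.

## The decoder

The core statistic is a cross-validated Mahalanobis-distance color decoder
operating on spatio-temporal EEG patterns.

**Patterns.** For the window-of-interest analysis, each trial's data in
100–400 ms after stimulus onset are baselined by subtracting the mean of that
same window (per trial and channel), averaged into consecutive 10 ms bins,
and the 17 posterior channels are concatenated: 17 × 30 = 510 dimensions per
trial (`windowPool()`). For time-resolved analyses, a 100 ms window slides
across the epoch; the window is demeaned, decimated by non-overlapping block
means to 100 Hz (voltage) or 125 Hz (alpha), and concatenated over channels
(`slidingPatterns()`). Where the output rate does not divide the window into
whole blocks (100 ms at 125 Hz = 12.5 samples) the window is truncated to the
largest whole number of blocks (12), dropping its earliest samples — a
documented convention, since ragged bins would make the dimensionality
ambiguous.

**Color bins.** Trial colors are assigned to the circularly nearest of 16
bin centers spaced 22.5° apart. Three rotations of the bin grid (offsets 0°,
7.5°, 15°) are analyzed and averaged so that no wheel color is systematically
near a bin edge (`colorSpaces()`, `assignBins()`; ties break toward the lower
bin index).

**Cross-validation and scoring.** Per color space and repetition, trials are
split into 8 random folds (stratified by bin for the time courses). In each
training set, bin counts are equalized by random subsampling, bin-average
patterns are smoothed across neighboring bins with a half-cosine basis
raised to the 15th power (`halfCosineBasis()`), and a shrinkage covariance is
estimated from the training trials after removing their own bin means
(`shrinkageCovariance()`, a Ledoit–Wolf convex combination of the sample
covariance and a scaled identity — guaranteed well-conditioned even with
510 dimensions and a few hundred trials). Each held-out trial's Mahalanobis
distances to the 16 smoothed bin means are mean-centered and sign-reversed,
and convolved with the cosine of the angular distance from the true bin:

accuracy = (1/16) Σₖ sₖ · cos(δₖ), with s = −(d − mean(d)).

Chance level is exactly 0; a flat distance profile scores exactly 0 and a
perfect cosine-shaped similarity profile scores 0.5. Distances use the
square-root (not squared) Mahalanobis form; the choice only affects the
arbitrary-unit scale, not signs or tests, and is fixed for reproducibility.
The 16-point profile reordered by signed angular distance from the true bin
is the *tuning curve*; averaged over trials it sums to zero by construction.
Everything is averaged over folds, repetitions (default 100) and the three
color spaces (`decodeWindow()`, `decodeTimecourse()`).

Design choices worth stating explicitly, where several readings were
defensible:

* Covariance residuals are the training trials minus their *own bin mean*
  (pooled across bins), not the grand mean.
* Basis smoothing is applied to the class means only, never to test trials.
* Subsampling equalizes to the minimum per-bin training count within each
  fold × repetition.
* The three color spaces are scored separately and their outputs averaged;
  nothing is re-fit across spaces.
* One seed per (participant, repetition) is derived from a deterministic
  Lehmer stream, so results are bit-reproducible while repetitions stay
  independent.
* The "moving average over a 10 ms window" downsampling is implemented as
  non-overlapping block means — this is what yields the stated 510-dimension
  pattern.
* The hot loop (fold scoring) is compiled (RcppArmadillo); a plain-R
  reference path built from the exported primitives is kept in the test
  suite and must agree to 1e-10.

## Alpha-power decoding

Alpha amplitudes are obtained per channel and trial by bandpass filtering at
8–12 Hz and taking the magnitude of the analytic (Hilbert) signal
(`alphaEnvelope()`). The filter is a zero-phase two-pass Hamming-window FIR
of order `3 * floor(fs / 8)` (the convention of the common EEG filtering
routines); epochs are reflection-padded with odd (point-symmetric) reflection
over at least three cycles of the low edge and the filter length. A pure
in-band sinusoid recovers its amplitude within 2% away from the outer
200 ms; a 25 Hz tone is attenuated below 1%. The outer ~100 ms of the
envelope still carries residual edge bias and should not be interpreted in
isolation. Time-resolved alpha decoding applies the identical sliding-window
decoder to the envelope, baselined over −200 to 0 ms.

## Representational similarity analysis

Bin-average patterns (first color space only) give a 16 × 16 matrix of
pairwise Mahalanobis distances, averaged over 100 bin-equalizing subsampling
repetitions (`computeRDM()`). Two model RDMs are regressed against it
separately (`fitModels()`): a *uniform* circular model (absolute angular
distance between bin centers) and a *primary-color* model in which each bin
belongs to the nearest of three primary hues and dissimilarity is binary
same/different category. The binary-category reading is the minimal
formalization of "differences explained by three discrete colors"; no
formula being canonical, it is fixed and documented here. Models are
z-scored over the off-diagonal, the strictly-lower 120 pairs are vectorized,
and the standardized slope (beta) is the fit statistic; z-scoring both sides
makes beta invariant to affine rescaling of either matrix and renders
"z-score the data too?" moot. Group inference is a sign-flip test on the
per-participant betas. The three primary hues default to the generator's
configuration; `estimatePrimaries()` (circular k-means, k = 3) can derive
them from behavioral reports instead.

## Group statistics

All group inference is permutation-based (`signflipTest()`): each
participant's statistic is negated with probability 0.5 (100,000 times by
default, or exhaustively when 2ⁿ patterns fit the budget), and the observed
group mean is ranked in the null. Monte-Carlo p values carry the +1
correction so they can never be zero; the floor is 1/(n_perm + 1).
Time-resolved series are corrected for multiple comparisons by cluster mass
(`clusterCorrect()`): points with pointwise permutation p below 0.05 form
contiguous same-sign clusters, the cluster mass is the sum of the group-mean
statistic, and each observed mass is ranked against the permutation null of
the *maximum* mass. Two deliberate choices: the cluster-forming threshold is
applied to pointwise permutation p values (keeping the machinery uniformly
permutation-based), and the same flip pattern is reused across all points of
a permutation — this preserves the autocorrelation of the series, which is
what makes cluster inference valid. Confidence intervals are percentile
bootstrap of the mean (`bootstrapCI()`). Condition contrasts are sign-flip
tests on per-participant differences (`pairedDifferenceTest()`). The tail is
always an explicit argument; nothing is hard-coded one- or two-sided.

## Behavioral repulsion analysis

The *adjusted error* is the signed circular difference between the report
and the center of the cued color's bin; positive means counterclockwise.
Errors are median-normalized within each cued-color bin (removing per-hue
idiosyncrasies), then binned by the cued−uncued difference into overlapping
22.5°-wide bins in 7.5° steps spanning −180° to +180° (`biasCurve()`).
Repulsion away from the uncued color appears as positive normalized error
for positive differences and negative for negative ones. The group test is
the cluster-corrected two-tailed sign-flip test over the difference axis,
treating the axis as circular (clusters may wrap at ±180°) — the axis *is*
circular, though a linear treatment would change little. The accuracy
screening statistic (proportion of trials within 30° of the target) is
reported by `behaviorSummary()` as quality control, not applied as a filter.

## The synthetic-data generator

`simConfig()` defaults encode the study conditions the package emulates:
30 participants × 1536 trials, 17 posterior channels at 500 Hz, four epochs
from −150 ms to the next stimulus onset (1100 ms after the items and the
cue; 600 ms after the impulse), 48 equidistant wheel colors.

The forward model is linear: per participant, Gaussian channel × bin tuning
maps W (voltage) and W′ (alpha) are drawn once from the participant seed, so
cross-participant pattern variability is realistic and all four epochs of a
participant share maps. A color θ contributes `amp · W b(θ) ⊗ s(t)`, where
b(θ) is the half-cosine tuning profile of θ against the 16 canonical centers
(width set by `tuningWidthDeg`, default 60° FWHM) and s(t) is a fixed
unit-energy transient spanning 100–400 ms. Event rules: the item-1 epoch
carries item 1 at `snrItem`; the item-2 epoch carries item 2 at `snrItem`
plus a residual item-1 trace at half that amplitude (the stored item remains
weakly decodable during the second presentation); the cue epoch carries no
evoked color signal; the impulse epoch carries the cued color at
`snrCuedImpulse` and the uncued color at `snrUncuedImpulse`. The ratio of
uncued to cued impulse amplitude is deliberately a free parameter — the
emulated experiment demonstrates the ordering, not a specific ratio — with
defaults 0.35 vs 0.8 (noise SD 1) chosen so that desk-scale cohorts
reproduce the ordering robustly without making the uncued trace trivially
strong.

From the cue epoch onward, a 10 Hz sinusoidal carrier with uniformly random
phase per trial adds `alphaAmp · W′ b(θ)`-patterned oscillations: random
phase guarantees the information lives in the amplitude envelope, not in the
phase, so voltage decoding of the cue epoch stays at chance while envelope
decoding succeeds. The carrier amplitude is modulated in time by a
deterministic event-locked partial desynchronization (a 100–400 ms dip,
depth 0.4) plus slow stochastic bursting (lowpassed below ~2 Hz, depth 0.3).
The event-locked component is essential, not decorative: the sliding-window
decoder removes each window's own mean, so a constant-amplitude carrier is
invisible to it, and purely stochastic fluctuations cancel out of the
condition averages. Only amplitude structure that is time-locked to the
event survives both operations — which is also the physiologically expected
signature (event-related alpha modulation).

Noise is Gaussian, white in time, with Toeplitz spatial correlation
`spatialCorr^|i−j|` across channels (full-rank, one parameter, and it
exercises the covariance shrinkage realistically).

Reports are the cued color plus von Mises noise (`reportKappa`, default 8 ≈
23° SD), plus a repulsion `repulsionAmpDeg · sin(Δ) · exp(−|Δ|/90°)` away
from the uncued color (odd in the cued−uncued difference Δ, zero at 0° and
180°, peaking near 66°), plus a pull of `primaryAttractionDeg · sin(3d)`
toward the nearest of three primary hues (d the signed distance to that
hue). Defaults (repulsion 5°, attraction 8°, primaries at 30°/150°/270°)
produce error histograms, primary-hue clustering, and a repulsion bias curve
of the qualitative shape and magnitude the paradigm reports.

What the generator does **not** emulate: raw continuous EEG, realistic ERP
morphology beyond the generic transient, eye movements or other artifacts,
1/f spectral structure or temporally correlated noise, and CIELAB rendering
(colors exist only as wheel angles). Passing tests therefore demonstrate
that the analysis machinery is correct and calibrated under the assumed
signal structure — not that any particular real dataset will yield the same
effects.

## Numerical and degenerate-input conventions

* All angles are degrees; signed circular differences live in (−180°, 180°].
* `shrinkageCovariance()` errors on zero-variance residuals rather than
  returning a singular matrix; `mahalanobisDist()` propagates the Cholesky
  failure on a non-positive-definite covariance rather than regularizing
  silently.
* `decodeWindow()` refuses to run when any bin has fewer trials than folds,
  naming the offending bin; `computeRDM()` requires two trials per bin.
* An RDM computed from identical patterns is all-zero, and fitting models to
  it raises a degenerate-fit error.
* Exhaustive sign-flip enumeration (including the identity flip) makes the
  smallest attainable p exactly 2⁻ⁿ; Monte-Carlo mode adds the +1
  correction.
* All randomness is derived from user-visible seeds through a Lehmer
  sub-seed stream; identical (config, seed) gives bit-identical output.

## Reduced desk-scale configuration

The test suite and the acceptance script run the full pipeline on reduced
problem sizes chosen as the package's standard desk-scale configuration:
cohorts of 8–20 participants, 512 trials (1536 for behavior-only analyses),
100 Hz simulation sampling, 50 ms pooling bins (17 × 6 = 102 dimensions),
5–10 fold/subsampling repetitions, and 20 Hz output rate for time courses.
These sizes preserve every structural property of the full-scale analysis —
the decoder is dimension- and rate-agnostic — while keeping a complete
cohort analysis in the minutes range on one core. Full-scale settings
(500 Hz, 10 ms bins, 100 repetitions, 100,000 permutations) remain the
defaults of the exported functions.

## Known limitations

* The envelope edge bias (outer ~100 ms) is flagged in documentation but not
  trimmed; time-course clusters touching the first or last window should be
  read with care.
* The primary-color model is binary same/different; graded categorical
  models are out of scope.
* No mixture modeling of guesses/swaps, no noise-ceiling estimation for the
  RSA fits, no cross-temporal generalization.
* Sign-flip inference assumes symmetric per-participant null distributions;
  decoding accuracies satisfy this under label exchangeability, but heavily
  skewed user-supplied statistics would not.
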