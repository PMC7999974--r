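---
title: "Sleep-stage connectivity with phase-locking values: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-stage connectivity with phase-locking values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvsleep)
```

## The analysis in one paragraph

plvsleep treats sleep staging as a functional-connectivity problem. A night
of multichannel EEG is cut into non-overlapping 30 s epochs labelled REM, N2
or N3; each epoch is decomposed into six canonical frequency bands (delta
0.5–4 Hz, theta 4–8, alpha 8–13, beta1 13–22, beta2 22–30, gamma 30–40); and
within each band the phase-locking value (PLV) is computed for every channel
pair, giving a symmetric C×C synchrony matrix per epoch whose upper triangle
(66 values for 12 channels) is the epoch's feature vector. Those vectors
feed three analyses: stage-average networks thresholded at the
no-isolated-node point, a point-biserial r² ranking of every (stage-pair,
band, channel-pair) feature, and a Gaussian-kernel SVM classifier run per
band and under three band-fusion strategies.

## The PLV statistic

For two phase series $\phi_a(t)$, $\phi_b(t)$ over one epoch of $T$ samples,

$$\mathrm{PLV} = \Bigl|\frac{1}{T}\sum_{t=1}^{T}
  e^{\,i(\phi_a(t)-\phi_b(t))}\Bigr| \in [0, 1].$$

PLV is insensitive to amplitude and to any fixed phase lag; it measures only
the *consistency* of the phase relation. Phases come from the analytic
signal (FFT construction) of each narrowband channel. Two numerical choices
matter:

* **Averaging convention.** The average runs over time samples within a
  single epoch, yielding one matrix per epoch — the per-epoch matrices are
  what classification needs, and stage-level summaries are obtained by
  averaging matrices across the epochs of a stage. (Averaging across epochs
  at fixed time is the other reading of the same formula; it produces no
  per-epoch features and is not implemented.)
* **Edge trimming.** The analytic transform is unreliable near epoch
  boundaries, so 0.5 s at each edge is excluded from the average
  (`edge_trim_s`, configurable). At 512 Hz this discards 512 of 15 360
  samples.

For independent uniform phases the expected PLV of a $T$-sample epoch is
$\sqrt{\pi/(4T)}$ — about 0.007 at $T = 15\,360$ — which is the noise floor
against which planted coupling is judged in the tests.

## Preprocessing and hypnogram curation

Recordings are re-referenced to the common average (CAR), band-passed
0.5–40 Hz, then split by a zero-phase Butterworth filter bank (order 4,
applied forward–backward). Zero-phase filtering is non-negotiable here:
a causal filter would add frequency-dependent phase lags that contaminate
every PLV downstream. All filters are `signal::butter`/`filtfilt`.

Stage labels near transitions are unreliable, so three deletion rules are
applied to the hypnogram before epochs are cut, in this order:

1. whole stage runs shorter than `min_run_epochs` (default 6 epochs =
   3 min) are dropped;
2. wake runs of at most `intrusion_max_epochs` (default 2 epochs) flanked
   by sleep on both sides are dropped along with one epoch on each side;
   the fragments this creates are re-checked against rule 1;
3. the first and last epoch of every surviving run are trimmed.

Only REM/N2/N3 epochs are kept (N1 is too brief and too ambiguous to
score reliably). The two thresholds are design choices — the clinical
literature gives examples, not cutoffs — and both are configurable. Short
wake runs that qualify as intrusions are exempted from rule 1 so that
rule 2 can remove their flanking epochs too; without the exemption rule 1
would silently swallow every intrusion first and the flanks would survive.
Epoch indexing is 1-based in R, with epoch $i$ covering samples
$[(i-1)\cdot 30 f_s + 1,\; i \cdot 30 f_s]$.

Component-based artifact removal (ICA and related classifiers) is out of
scope; an optional peak-amplitude epoch-rejection hook
(`amplitude_reject_uv`, disabled by default) stands in for it.

## The synthetic generator and its calibration

Real polysomnography cannot ship with a package, so every downstream stage
is exercised on synthetic epochs with *known* coupling. Per band, the
generator draws a shared narrowband carrier (band-pass filtered Gaussian
noise, so the analytic phase is well defined and the spectrum is EEG-like
rather than a pure tone), and gives each channel a copy whose instantaneous
phase is perturbed by an independent, slowly varying Gaussian jitter
(order-2 low-pass at 1 Hz, rescaled to an exact marginal sd). Channel
signals sum the six band components, amplitude-weighted with a rough 1/f
fall-off, plus white noise.

If the pairwise phase difference is wrapped-normal with sd $\sigma$, its
expected PLV is $e^{-\sigma^2/2}$ — the closed form that calibrates the
generator. Under the shared-carrier convention the pairwise difference of
two channels jittered with $\sigma_i$, $\sigma_j$ has
$\sigma_\mathrm{eff}^2 = \sigma_i^2 + \sigma_j^2$, so a uniform pairwise
target $\sigma$ is realized by giving every channel $\sigma/\sqrt2$; a
general pairwise sigma matrix is realized in least squares (exact whenever
the matrix is additively consistent). The calibration checks the *pairwise*
convention: measured mean PLV across 200 generated epochs stays within 0.05
of $e^{-\sigma^2/2}$ over $\sigma \in \{0, 0.3, 0.6, 1.0, 1.5\}$ and is
strictly decreasing.

Why slowly varying jitter rather than per-sample? A white phase error is
spectrally broad: band-pass filtering in the measurement chain would remove
most of it and the measured PLV would land far above the closed-form
target. Jitter band-limited to 1 Hz survives the measurement filters, at
the cost of fewer effective independent samples per epoch (roughly
$2BT \approx 60$), which leaves a small positive bias in the measured
resultant — about 0.01 at $\sigma = 1.5$, inside the calibration tolerance.

The default coupling table plants the stage contrasts the pipeline is meant
to detect: PLV increasing from N2 to N3 in delta and alpha, decreasing in
beta2 and gamma, overall PLV falling from low to high bands with alpha
sitting above theta. Magnitudes are package choices (no published effect
sizes exist for these contrasts); they are set large enough that a
75-epoch dataset resolves them at $p < 0.001$ but far from saturation.
Presets cover the other experimental conditions: `coupling_band_contrast()`
(contrast in one band only), `coupling_complementary()` (each of three
bands separates one stage from the other two — no single band suffices,
their union does), `coupling_zero_contrast()` (chance floor), and
`coupling_calibration()` (single active band for the closed-form check).

What the generator does *not* emulate: sleep microstructure (spindles,
K-complexes), 1/f broadband slope beyond the amplitude weights,
non-stationarity within epochs, artifacts, or volume conduction. Passing
tests therefore demonstrate that the *pipeline* recovers planted coupling
statistics, not that real sleep EEG behaves like the generator. One
consequence of the carrier model worth knowing: band-edge spectral leakage
makes a strongly coupled band bleed a little contrast into its spectral
neighbours (alpha into theta/beta1), exactly as a real oscillation
overlapping a band boundary would; tests that need spectral isolation use
non-adjacent bands.

## Band evaluation

Each feature's discriminability for a stage pair is the point-biserial
r²:

$$r = \frac{\sqrt{N_+ N_-}}{N_+ + N_-}\,
      \frac{\overline{X_+} - \overline{X_-}}{\mathrm{sd}(X_+ \cup X_-)},
      \qquad r^2 \in [0, 1],$$

with the *population* sd of the pooled sample, which makes $r^2$ exactly
the squared Pearson correlation with a 0/1 class indicator and exactly 1
under perfect separation of two constant groups. (The widely printed
variants of this formula differ in the prefactor; this is the standard
form, verified in the tests against the Pearson identity on a thousand
random cases.) The 3 × 66 × 6 scores are ranked globally with
deterministic tie-breaks (r² descending, band order, pair index).
Summaries: the band shares of the top-k records (k = 95 and 140 by
default, pooled across stage pairs), the per-stage-pair discriminative
ratio (share of summed r² among the top t = 36 records), and the two
best features per band by stage-pair-averaged r² for 2-D scatters.

## Classification and fusion

The classifier is libsvm's C-SVC (via e1071) with a Gaussian kernel and
one-against-one multiclass voting — libsvm is the implementation the
original analyses in this field use. Features are standardized with
training-set statistics; defaults are $C = 1$ and
$\gamma = 1/d$ on standardized features. Hyperparameters were not tuned;
both are exposed.

* **Feature-level fusion ("C")** concatenates band feature blocks
  (6 × 66 = 396 columns for all six bands).
* **Decision-level fusion ("E")** trains one SVM per band and a meta-SVM
  on the base classifiers' per-class decision scores. Scores, not hard
  labels, are used (strictly more informative); they are aggregated from
  the signed pairwise decision values rather than Platt-scaled
  probabilities because libsvm's probability fit is internally randomized
  and would break reproducibility. Meta-training uses out-of-fold scores
  from an internal seeded 5-fold split of the training data, so the meta
  classifier never sees a base classifier's predictions on its own
  training points, and the test split is untouched until evaluation.
* **Hybrid fusion ("E(C)")** feature-fuses band pairs (delta+beta1,
  theta+gamma, alpha+beta2 by default) and stacks the pair classifiers.

Splits are stratified 75/25 with an explicit seed. Reports carry accuracy,
per-class true-positive rates and the confusion matrix, with the arithmetic
invariants (rows sum to class counts, accuracy = trace/total) asserted in
tests for every run.

## Problem sizes and degenerate inputs

The test and demonstration datasets run at 128 Hz sampling with 2–12
channels and 24–90 epochs — the package's fast-experiment defaults; the
pipeline itself is rate-agnostic and handles the native 512 Hz unchanged
(one 512 Hz segmentation check runs in the tests). Degenerate inputs fail
loudly: single-channel CAR, all-zero channels at phase extraction, bands
outside Nyquist, empty hypnograms, single-class training sets,
zero-variance features in r², and mismatched band orderings in fusion all
raise errors rather than returning quiet nonsense. Ties in the no-isolate
threshold are resolved by keeping edges at exactly the threshold
(`w >= tau`), which is what makes the closed form
$\tau = \min_i \max_{j \ne i} w_{ij}$ exact.

## Known limitations

* PLV inherits volume-conduction sensitivity; zero-lag spread inflates it.
  Metrics that discount zero-lag coupling (PLI and relatives) are outside
  scope.
* The EDF reader covers plain continuous EDF with a single sampling rate;
  EDF+ annotation streams and mixed-rate signals are rejected.
* Stage-average networks use only degree/isolation; no further graph
  metrics.
* Classification quality on real recordings depends on curation quality;
  the deletion-rule thresholds here are defensible defaults, not clinical
  constants.
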