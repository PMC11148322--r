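---
title: "Multimodal assessment of bulbar motor involvement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal assessment of bulbar motor involvement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmbulbar)
```

## The measurement problem

Bulbar involvement in amyotrophic lateral sclerosis (ALS) degrades the
neuromuscular control of the speech and swallowing musculature long before
overt symptoms appear. `mmbulbar` implements a fully automated measurement
pipeline over two noninvasive, clinically available signal modalities
recorded simultaneously during a speech task:

* a mono audio waveform at 22,050 Hz, and
* three surface-EMG channels at 2,000 Hz from the right anterior temporalis
  (RTEMP), right masseter (RMAS), and right anterior belly of digastric
  (RABD) — two jaw elevators and one jaw depressor.

From each speech sample the pipeline extracts 60 features spanning seven
constructs of bulbar/speech motor control — prosody (3), pause (3),
functional connectivity (9), amplitude (4), rhythm (21), complexity (16),
and regularity (4) — and a statistical layer turns feature tables into
composite outcome measures: Cohen's-d effect-size screening, a 10-factor
confirmatory factor model with Bartlett scores, Cronbach's alpha
reliability, and repeated cross-validated machine-learning regression and
classification.

Because clinical recordings of this kind are not publicly distributable,
the package ships seeded generators (`make_speech_audio()`,
`make_semg_triplet()`, `make_cohort()`, `make_factor_table()`) that emit
signals with *known* ground truth (pause schedule, f0 contour, shared-drive
coupling, modulation depth, latent factor structure), so every stage can be
verified against an independent oracle.

## Signal pipeline

### Preprocessing and epoching (sEMG)

Each sEMG channel is notch-filtered at 60 Hz (second-order IIR, Q = 30) and
high-pass filtered at 20 Hz (4th-order Butterworth), both applied
forward–backward for zero phase, and the DC offset is removed. All
zero-phase filtering in the package uses odd-reflection padding at both
ends so filter transients decay inside the pad rather than in the signal.

For the coherence analysis the rectified channels are reduced to
concatenated stationary 1-s epochs centred on activity bursts. The burst
detector is the package's own design (the reference procedure does not
define one): the 100-ms moving-RMS envelope is thresholded at
`q10 + 0.25 (q90 − q10)` of its own distribution, sub-threshold dips
shorter than 0.2 s are bridged (the drive-modulated envelope dips inside a
burst), supra-threshold runs of at least 0.2 s become bursts, and runs
longer than 1 s are tiled. An early design used the envelope's
lowest-quartile median + 3 MAD as the threshold; it proved fragile when the
quiet fraction of a recording is small (the MAD is inflated by mixture
contamination and the threshold can exceed the burst level), which is why
the quantile-contrast rule replaced it. A minimum-contrast gate
(`q90 − q10 < 0.5 × median`) classifies flat or noise-only envelopes as
containing no activity, so silence raises an explicit error instead of
producing arbitrary epochs. Epochs whose first/second-half RMS ratio
exceeds 3 are discarded as non-stationary. In the full pipeline the epoch
windows are selected once, on the mean rectified envelope of the three
channels, and applied to all channels, keeping the pair spectra
sample-aligned.

### Pause/speech segmentation and prosody

Segmentation thresholds follow established speech-pause-analysis practice:
minimum pause duration 150 ms, minimum speech-event duration 35 ms,
amplitude threshold 0.04. The amplitude threshold is interpreted as a
fraction of the sample's peak absolute amplitude, applied to a 10-ms RMS
envelope, which makes the segmentation invariant to recording gain; an
absolute silence floor (`1e-5` full scale) catches all-silent samples. The
two duration thresholds are scaled by `160 / speaking rate (WPM)`, so
slower speakers get proportionally longer minimum durations; the direction
of this scaling is a config switch (`seg_params(scale_direction=)`).

f0 is tracked by frame-wise normalized cross-correlation (20-ms windows
for male, 10-ms for female voices; search ranges 60–300 / 100–500 Hz;
voicing threshold 0.5; parabolic peak refinement). Prosody features are
the sample SD, interquartile range, and mean of the voiced f0 values on a
semitone scale with a 1-Hz reference — only the mean depends on the
reference, and sample SD (not population) is used throughout.

### Intermuscular coherence

Welch auto- and cross-spectra use a 1,024-point Hamming window at 75%
overlap, zero-padded to a 4,096-point FFT, over the rectified epoched
channels; coherence is `|Sxy|² / (Sxx Syy)` per bin. The adjusted
independent-segment count is `L̂ = 0.52 K` for `K` overlapped windows (the
variance-equivalent correction for a Hamming window at 75% overlap; the
factor is exposed in `coherence_params()` since the literature's exact
adjustment is not published), and the significance level under
independence is `S = 1 − 0.05^(1/(L̂−1))`. Mean coherence is computed per
muscle pair in theta/alpha (4–12 Hz), beta (12–30 Hz), and low-gamma
(30–60 Hz) bands with half-open `[lo, hi)` membership; band means below
`S` are set to zero, so gated features are either 0 or at least `S`.

### Amplitude via visibility graphs

The signal is reduced to a local-SD series over non-overlapping 50-ms
blocks (1,103 samples for audio — kept at the literature's printed value
although 22,050 × 0.05 = 1,102.5 — and 100 for sEMG; the partial final
block is dropped), converted to a natural visibility graph with a strict
inequality (collinear points are not visible), and summarized by the graph
density `2m / (M(M−1))`. The construction is the naive `O(M³)` scan, which
at `M ≈ 70–90` vertices per sentence costs little and doubles as its own
oracle. Density is invariant to amplitude scaling, hence calibration-free.

### Rhythm

Envelopes are Hilbert envelopes (analytic signal via FFT) resampled to
100 Hz after pause excision. The acoustic waveform is band-pass filtered
*in the spectral domain* into 28 narrow bands whose edges are equally
spaced on the ERB-rate (cochlear) scale between 100 and 10,000 Hz; each
band's analytic signal is reconstructed at baseband from its own FFT bins
(an exact downsampling of the full-rate analytic narrowband signal), and
narrow-band envelopes whose centre frequency falls inside a critical band
are averaged into the four critical-band envelopes: 100–300 (pitch),
300–800 (F1), 1,000–3,000 (F2), 3,000–8,000 Hz (consonant noise). Centres
in 800–1,000 and 8,000–10,000 Hz belong to no critical band by design.

Theta (2.5–12 Hz) modulation depth is the fraction of the demeaned
envelope's power spectrum (2,048-point FFT, Hamming) inside the theta
band, normalized by the total power above DC. The DC bin is excluded
deliberately: the raw envelope mean would otherwise dominate the "total
spectral power" and saturate the metric near zero for every signal.

Phase synchronization between timescales uses 4th-order zero-lag
Butterworth band-passes into delta (0.9–2.5 Hz), theta, and beta/gamma
(12–40 Hz) components ("4th order" is read as the MATLAB `butter(4, ...)`
convention, i.e. 4th-order roll-off per band edge; a 2nd-order prototype
leaks neighbouring tones enough to visibly corrupt the phase of locked
pairs). The index is the modulus of the time-averaged phasor of the
generalized phase difference `n φ₁ − m φ₂` (2:1 for delta–theta, 3:1 for
theta–beta/gamma) with instantaneous phases from the analytic signal and a
10% margin trimmed at each end. As printed in the source, the defining
expression lacks the averaging operator — the modulus of a unit phasor
would be identically 1 — so the time average is taken as the standard n:m
index in the literature.

### Complexity (RQA)

Series are z-scored, delay-embedded, and two points are recurrent when
their Euclidean distance is at most `ε ×` the maximal pairwise distance of
the embedded series (this normalization makes the published thresholds
scale-free; the convention is exposed in `rqa_params()`). The line of
identity is excluded (Theiler window 1), minimal diagonal length 2, and
determinism is the fraction of recurrence points on diagonals of at least
that length. sEMG uses `(m = 30, τ = 5, ε = 0.1)` on non-overlapping 1-s
segments averaged per channel; the acoustic signal is reduced to 13 MFCCs
(25-ms Hamming frames, 10-ms hop, 26 mel filters, DCT-II coefficients
1–13, excluding the energy coefficient) and each coefficient series gets
`(m = 3, τ = 15, ε = 0.2)`.

### Regularity (wavelet packet entropy)

A 3-level wavelet packet decomposition (Daubechies-4 extremal-phase
filters, periodized convolution, natural frequency ordering via Gray-code
reordering) produces eight subband coefficient vectors whose energies
partition the input energy exactly; periodization was chosen over
symmetric extension precisely so Parseval holds to machine precision.
All coefficients are normalized jointly to unit total energy and each
node's Shannon entropy `−Σ s² ln s²` is averaged over the eight nodes.
Joint (rather than per-node) normalization is deliberate: per-node
normalization makes a pure tone — whose coefficients are maximally
time-spread within its band — score *higher* than broadband noise,
inverting the irregularity ordering the feature exists to capture. With
joint normalization a node holding all the energy in one coefficient
scores 0 and a node holding all of it spread over `N` coefficients scores
`ln N`, and noise scores above a tone.

## The synthetic study conditions

`make_cohort()` emulates a two-group reading-passage study: by default 19
sentences per participant (437 samples for a 13 + 10 cohort), speech time
per sentence uniform on 3.6–4.3 s, two interior pauses per sentence whose
durations *extend* the sentence (the sentence text is fixed, so pausing
lengthens the recording rather than eating speech time), a
piecewise-constant f0 contour over ~0.6-s sub-chunks jittered in
semitones, theta-rate amplitude modulation around 4.5 Hz shared between
the audio and the sEMG burst envelopes (jaw muscles contract
syllabically), slow broadband (0.5–20 Hz) envelope fluctuation emulating
natural amplitude irregularity — this is what keeps theta modulation depth
away from saturation and makes it responsive to the scheduled depth — and
sEMG channels mixing a shared band-limited oscillatory drive (8–12 and
15–25 Hz) with private noise under a burst envelope with 50-ms
raised-cosine ramps.

Participant-level baselines (means and jitter SDs chosen once as plausible
for a clinical speech cohort) are: coupling 0.60 (SD 0.08), AM depth 0.55
(0.08), pause duration 0.25 s (0.05), f0 variability 1.5 st (0.4),
speaking rate 180 WPM (20). Group effects are injected at the *signal
parameter* level in units of these SDs (`effect_map`), so the entire
extraction chain is exercised end-to-end rather than shifting features
directly.

What the generator does *not* emulate: intelligible phones, formant
transitions, motor-unit action-potential shapes, electrode artifacts, or
inter-muscle latency differences. Passing tests therefore demonstrate that
the pipeline measures what it claims on signals with known structure, not
that the features are clinically discriminative on real patients.

One consequence of realistic per-participant parameter jitter deserves
emphasis: with repeated sentences per participant, rows of one participant
land in both training and test folds of a sample-level cross-validation,
and participants are nested in groups, so even a cohort generated with *no*
group effect classifies well above chance from participant idiosyncrasies
alone. The exchangeable null is therefore label permutation at the sample
level, which is how the package's null-classification checks are
formulated. (The same repeated-measures caveat applies to the original
study design, which its authors acknowledge.)

## Statistical layer

* `cohens_d_screen()` uses the pooled-SD d with pairwise-complete
  observations and retains `|d| > 0.5`.
* `fit_cfa()` estimates the simple-structure model (each feature on
  exactly one factor, factor variances fixed at 1, correlations free) by
  ML discrepancy minimization (`nlminb`, factor correlation matrix
  parameterized through row-normalized Cholesky factors). Features with a
  loading below 0.5 are pruned and the model refit once. CFI and RMSEA
  come from the chi-square against the diagonal independence baseline.
  Factors reduced to a single indicator are fixed (loading
  `sqrt(1 − 0.001)`, uniqueness 0.001) so the factor reproduces its item
  while Bartlett weighting stays well-defined. Bartlett scores
  `(ΛᵀΨ⁻¹Λ)⁻¹ΛᵀΨ⁻¹ z` are conditionally unbiased for the generating
  factors (checked by regression slope in the tests). Two degenerate-input
  behaviours are deliberate: on a truly null structure the per-factor
  loading vector is unidentified (the optimizer's conservative 0.3 start
  keeps it near zero rather than hallucinating structure), and
  near-boundary uniquenesses are flagged as Heywood cases.
* `cronbach_alpha()`, `summary_f_test()` (pooled-variance one-way ANOVA
  from (M, SD, n) summaries — it reproduces a full ANOVA on any raw data
  with those summaries), `chi2_yates()` (the continuity correction is
  required to reproduce the published sex comparison), and `bh_fdr()`
  complete the layer.
* `cv_evaluate()` runs k-fold cross-validation repeated R times (default
  5 × 10), stratified for classification, pooling out-of-fold predictions
  within each repeat and averaging metrics over repeats; all randomness
  derives from one seed, making metrics bit-reproducible. Learners are a
  500-tree random forest, an RBF-kernel SVM (`γ = 1/(p·var)`, cost 1,
  fold-internal standardization), and a linear model as the regression
  benchmark; these hyperparameters are stated here because the reference
  analysis does not publish any. Multiclass AUC is the mean of pairwise
  one-vs-one AUCs.

## Problem sizes and numerical choices

The test-suite and acceptance runs use the cohort at its study cardinality
(23 participants × 19 sentences = 437 samples) with the RQA segment count
capped at one 1-s segment per channel (`extract_config(rqa_max_segments =
1)`), the documented reduced setting for batch runs; single-sample
extraction defaults to all segments. Monte-Carlo checks use 10–20 seeds;
CFA recovery uses n = 2000. Large FFTs are padded to 2·3·5-smooth lengths
(R's mixed-radix FFT degrades badly on lengths with large prime factors);
envelopes are decimated in stages with 4th-order Butterworth anti-alias
filters. Ties in the visibility criterion are non-edges (strict
inequality); a single pause has SD 0 by convention; zero-recurrence plots
have DET 0 with a warning; zero-energy wavelet input is an error.

## Known limitations

* The burst detector and stationarity proxy are package-defined stand-ins
  for an unpublished procedure; their constants live in `burst_config()`.
* The `L̂ = 0.52 K` overlap correction is a documented approximation.
* MFCC framing, the mel filter count, the wavelet family, and the entropy
  normalization are package choices where the reference is silent.
* The synthetic cohort's effects are monotone parameter shifts; real
  disease effects are heterogeneous across participants and constructs.
* Mixed-effects modelling of factor scores (and listener-based
  intelligibility scoring) is out of scope; the package emits the
  per-sample feature and factor-score tables such analyses consume.
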