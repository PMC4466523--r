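---
title: "Detecting nasal vowels from surface EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nasal vowels from surface EMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasemg)
```

## The problem

European Portuguese distinguishes oral from nasal vowels; nasality is
produced by lowering the velum (soft palate) so the velopharyngeal port
opens into the nasal cavity. A silent-speech interface built on surface
electromyography (EMG) of the face and neck needs to detect that
movement, but the muscles involved are deep, the surface signal is weak,
and cross-talk from jaw and tongue muscles is strong. The approach
implemented here uses a second modality as ground truth: real-time MRI
(RT-MRI) of the vocal tract, acquired at 14 frames/s in a separate
session, gives the velum aperture directly. The two recordings are
bridged through their audio tracks, so that aperture-derived nasal
intervals can label the EMG timeline, and a frame-level classifier can
then be trained and evaluated on the EMG alone.

`nasemg` implements that pipeline end to end, together with a synthetic
scenario generator with known ground truth, so that every stage is
verifiable on a desk without the original recordings.

## Pipeline stages

### 1. Velum aperture from image sequences

In a mid-sagittal slice the airway between velum and pharyngeal wall is
hypo-intense (dark). Inside a fixed region of interest (ROI),
`segment_sagittal()` grows a connected region of pixels below an
intensity threshold from a single seed, with 6-connectivity in
(t, y, x): face adjacency in space *and time*. Because the neighborhood
includes the time axis, one seed in one frame suffices to track the
airway through the sequence. The per-frame pixel count of the grown
region is the area curve: minima are a closed port (oral), maxima an
open port (nasal). `segment_coronal()` applies the same growth to
coronal-oblique stacks, with several seeds and a configurable intensity
polarity, since what counts as "the compartment" differs by slice and
sequence contrast.

Numerical choices: the hypo-intensity threshold defaults to 0.5 of the
normalized intensity range and is an explicit parameter (the original
workflow seeded interactively; a fixed threshold makes the operation
reproducible); connectivity is the simplest face-adjacent 3-D
neighborhood; coordinates are 0-based `(frame, row, col)`.
`area_to_velum_curve()` min-max normalizes the areas to [0, 1] and
attaches the mean x̄ and the *population* standard deviation σ (the
divisor-N convention is fixed here for reproducibility; with curves of
dozens to hundreds of frames the difference from the sample SD is
negligible). A constant area curve cannot be normalized and is returned
flagged degenerate: no nasality is detectable from it.

### 2. Cross-modal alignment

Both recordings carry audio. Each track is resampled to a common
12000 Hz (`resample_audio()`, polyphase band-limited resampling), then
reduced to a short-time log-energy envelope (25 ms window, 10 ms hop,
floored at −60 dB). `dtw_align()` runs dynamic time warping on the two
envelopes with squared-difference local cost, step set
{(1,1), (1,0), (0,1)} and a Sakoe–Chiba corridor of 10% of the longer
envelope. Envelope DTW rather than sample-level DTW is a design choice:
sample-level alignment at 12 kHz is quadratically expensive and
phase-fragile, while syllable-scale energy landmarks are what actually
constrains the warp. Ties among equal-cost steps prefer the diagonal,
then (1,0), then (0,1), fixing the path deterministically. The corridor
is defined by the symmetric criterion |i·(M−1) − j·(N−1)| ≤ W so that
swapping the inputs leaves the reachable cell set, and hence the optimal
cost, unchanged.

`warp_time_map()` collapses the (possibly many-to-one) path to a
single-valued monotone time map by taking the median EMG-side index per
MRI-side index, with a running-maximum guard; `warp_curve()` composes
the velum curve with that map and resamples it onto the 600 Hz EMG
clock by linear interpolation, which cannot overshoot the source range.

### 3. Nasal / non-nasal zoning

On the (renormalized) warped curve, samples with x(n) ≥ x̄ + σ/2 are
candidate-nasal. To include the whole transitional part of the movement
(lowering and raising of the velum), each candidate run is widened by a
triangle construction: with the nearest peak (t_p, y_p) and the adjacent
crossing of the curve with its mean (t_c, x̄), two congruent right
triangles sharing the apex angle give a horizontal extension

v₂ = x̄ · |t_c − t_p| / (y_p − x̄),

and the boundary moves to t_c − v₂ (rising edge) or t_c + v₂ (falling
edge). The prose and figure this construction derives from admit more
than one geometric reading; the formalization above is one consistent
reading, fixed and unit-tested, not asserted as the only possible one.
When a run contains several peaks (a velum that stays open longer than
one pulse), the first peak drives the rising-edge geometry and the last
peak the falling-edge geometry. Local maxima are samples strictly above
both neighbors, plateaus contributing their midpoint. Extended runs are
merged if they overlap; the complement becomes non-nasal zones, and a
per-sample 0/1 square wave is emitted. All intervals are half-open
[start, end) in seconds; frames are labeled by the zone containing
their temporal midpoint (unbiased, order-independent, and cheap — the
alternative majority-of-samples rule gives the same label except for
frames straddling a boundary).

### 4. EMG conditioning, framing, features

`preprocess()` max-abs-normalizes each channel to [−1, 1], rectifies,
and smooths with a 12-point moving average applied forward and backward
(reflect padding), so the net 23-tap response is exactly zero-phase on
the sample grid — an even-length single-pass boxcar cannot be.
Normalization is max-absolute because it preserves the zero baseline
that rectification assumes.

`frame_signal()` cuts 100 ms frames advanced by 20 ms (half-open sample
index ranges, trailing partial frame discarded), and
`extract_features()` computes nine first-order temporal features per
frame: mean, absolute mean, standard deviation, maximum, minimum,
kurtosis, energy, zero-crossing rate, mean absolute slope. Conventions
fixed here (the feature-list tradition these come from leaves them
open): population SD; excess kurtosis with the population estimator,
defined as 0 for a constant frame; energy as the mean of squares
(length-invariant); ZCR as sign changes over L−1 with zeros inheriting
the previous sign; mean absolute slope over L−1. By default features
are computed on the *normalized raw* signal, not the rectified/smoothed
one: rectification and heavy smoothing destroy the zero-crossing rate
and flatten kurtosis, two of the nine features. The
`features_on = "preprocessed"` switch exposes the alternative, since
which variant the original study classified is not stated.

### 5. Classification and reporting

`crossvalidate()` runs stratified 10-fold cross-validation with seeded
shuffling: per fold, features are standardized on the training part,
an RBF-kernel SVM (`e1071::svm`; C = 1, γ = 1/(d · mean feature
variance), both configurable) is trained and evaluated on the held-out
part. Error rate, sensitivity and specificity (nasal = positive class)
are reported per fold with means and t-based 95% confidence half-widths
(mean ± t₀.₀₂₅,ₖ₋₁ · sd/√k). Folds are stratified at frame level,
matching the pooling of frames into one set; note that overlapping
frames can straddle folds, an optimistic bias frame-level pooling
cannot avoid — which is one reason synthetic results here should be
read as pipeline verification, not as predicted real-data accuracy.

`zone_majority()` classifies each zone from its frames' predictions:
nasal iff nasal-predicted frames are *equal to or more numerous* than
non-nasal ones (ties go to nasal), optionally restricted to an
[a%, b%] sub-interval of each zone. `combine_channels()` concatenates
per-channel feature blocks in channel-id order for multi-channel
classification. `class_distribution()` reports counts with percentages
rounded half-up to one decimal.

### 6. Dependence measures

`mutual_information()` is the plug-in estimator on an equal-width joint
histogram (default 16 bins per axis, base-2 logarithm): I(X;Y) =
ΣΣ p(x,y) log₂(p(x,y)/(p(x)p(y))), empty cells contributing 0. The
normalized variant divides by √(H(X)·H(Y)) by default (I/min(H) and
I/mean(H) are selectable, since normalized-MI conventions vary), and is
defined as 0 when either marginal entropy is 0. `zone_dependence()`
evaluates MI, normalized MI and Pearson r per zone class and overall.
The plug-in estimator is positively biased at finite n — roughly
(B−1)²/(2N ln 2) bits for B bins — so small MI values on short segments
should be compared between conditions, not read as absolute dependence.

## The synthetic generator

`make_scenario()` generates, from one `scenario_config()` and one seed:

- a ground-truth aperture curve: baseline 0 with one raised-cosine pulse
  of peak 1 per nasal event (overlaps merged by pointwise maximum), and
  the exact half-open nasal intervals;
- 5-channel EMG at 600 Hz: Gaussian baseline noise plus band-limited
  (60–200 Hz) stochastic bursts under a cosine-tapered envelope whose
  half-cosine ramps last `burst_lead`; the envelope starts `burst_lead`
  before each nasal onset and the burst is scaled so its RMS over the
  support is `burst_snr` times the noise RMS, then channels are mixed by
  a crosstalk matrix;
- paired audio: tone-complex "syllables" (one per event, cycling
  fundamentals) rendered at 8000 Hz on the EMG side and, through a
  configurable piecewise-linear strictly monotone warp, at 16000 Hz on
  the MRI side, with the true warp returned;
- optionally a toy image stack: bright background (≈0.8), dark region
  (≈0.1) inside the ROI whose per-frame pixel count is an affine
  function of the aperture value, plus intensity noise.

Default conditions, chosen once as a realistic desk-scale regime:
0.5 s open duration and 1.1 s onset spacing (≈45% nasal duty, so frame
and zone classes are near-balanced, as in the corpus statistics the
design mirrors); burst SNR 4; `burst_lead` 0.10 s — no quantitative
lead time between EMG activity and velum movement is established for
this muscle group, so this is a simulation parameter, not a measured
value; burst duration 0.60 s (= lead + open duration), so activation
rises before the opening and is sustained across the open phase, which
is what overlaid aligned EMG/aperture traces motivate — with bursts
confined to a short onset transient, nasal-zone frames would be mostly
indistinguishable noise and the generator would not emulate the regime
the method is reported to operate in; optional closing-movement bursts
(off by default); per-channel burst gains (0.6, 1, 1, 1, 0.6) so the
middle channels carry the clearest velum-related activity; mild
crosstalk (0.05 spread off-diagonal).

What the generator does *not* emulate: real EMG spectra and motor-unit
statistics, speech acoustics (the tone complexes only provide alignment
landmarks), MRI intensity bias and motion artifacts, session-to-session
electrode variability, and jaw/tongue cross-talk correlated with
articulation. Passing tests therefore demonstrate that the pipeline's
machinery is correct and recovers known ground truth under its stated
assumptions — not that any particular accuracy carries over to real
recordings.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run synthetic scenarios of 5–40
utterances (≈6–45 s of signal), image stacks of 64×64 pixels at 14 fps,
and alignment problems of a few hundred envelope frames; these sizes
were chosen so a complete verification runs in well under an hour on a
single core while every stage still operates far from trivial regimes.

Degenerate inputs are handled explicitly rather than silently: constant
area curves return a flagged all-zero aperture curve; `detect_zones()`
and `compute_threshold()` refuse degenerate curves; all-zero EMG
channels skip normalization and are flagged; signals shorter than one
analysis window, empty warp paths, single-class label sets, and
out-of-span frames are errors.

## Known limitations

- The triangle boundary extension is one reading of an ambiguous
  construction; alternatives would shift zone edges by fractions of v₂.
- Envelope DTW recovers warps to roughly one MRI frame period; it is not
  a forced aligner, and drift inside long silences is unconstrained.
- Frame-level fold pooling lets overlapping frames straddle folds;
  utterance-level grouping (`stratified_folds()` on utterance ids) is
  the conservative alternative.
- The plug-in MI estimator is biased upward at small n; comparisons are
  meaningful, absolute values less so.
- The corpus adapter (`read_deposited_corpus()`) is a tolerant
  best-effort mapping and is exercised only against directories written
  by this package's own writers.

## A worked example

```{r example, eval = FALSE}
library(nasemg)

man <- run_pipeline(list(
  pipeline = list(seed = 1, out = "run1"),
  scenario = list(n_utterances = 40, burst_snr = 4)))

print(man$results$cv)      # per-fold error / sensitivity / specificity
man$results$zone_majority$error
man$results$dependence     # MI and Pearson r by zone class
```
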