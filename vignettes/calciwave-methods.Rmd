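---
title: "calciwave: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{calciwave: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciwave)
```

## What the package computes

calciwave analyzes fluorescence time-series movies of neuronal cultures
expressing a fast genetically encoded calcium indicator (GCaMP6f-class).
Activity in such cultures appears as calcium transients — fast-rising,
slower-decaying fluorescence excursions of individual somata — that, as
networks mature, organize into near-simultaneous population bursts. The
pipeline turns a raw `T x H x W` movie into per-neuron descriptors in four
stages:

1. **Segmentation.** A maximum-intensity projection (MIP) across all
   frames is converted to 8-bit, contrast-stretched, thresholded,
   despeckled, opened, watershed-split, and labeled by size-limited
   particle analysis. This is the classic ImageJ macro chain for isolating
   active somata: a neuron that fires at least once during the acquisition
   leaves a bright blob in the MIP.
2. **Trace extraction.** For each ROI, `F(t)` is the mean intensity over
   its pixels and is normalized as `dF = (F - F_min) / F_min`, where
   `F_min` is the exact per-ROI minimum over the acquisition. The per-ROI
   minimum of `dF` is therefore exactly zero, and `dF` is invariant to any
   multiplicative gain of the camera.
3. **Bilevel waveform analysis.** Each `dF` trace is treated as a
   two-state (baseline/active) signal. State levels are the modes of the
   lower and upper halves of the trace's 100-bin amplitude histogram.
   Reference levels at 10%/50%/90% of the state-level span define pulses:
   a pulse is a consecutive pair of positive- and negative-going
   50%-crossings (linearly interpolated); rise time runs from the 10% to
   the 90% upward crossing, fall time symmetrically downward; slew rates
   divide the 10–90% span by those times. Per-ROI features are **amplitude**
   (state-level span), **pulse width** (mean 50%-to-50% duration),
   **frequency** (reciprocal of the mean interval between successive pulse
   onsets — the inverse inter-burst interval, not a within-burst spike
   rate), **rise/fall time**, **slew rates**, and **duty cycle**
   (mean width / mean period).
4. **Synchrony and variability.** Traces are thresholded at `dF > 0.15`
   (sub-threshold values zeroed) to exclude baseline fluctuations, the
   pairwise Pearson matrix is computed over frames, and each neuron's
   synchrony is its mean correlation across all pairings. Variability is
   summarized as percent coefficients of variation (sample SD / mean x
   100) at three scopes: across fields (spatial), across serial
   acquisitions of one field (temporal), and across ROIs within one
   acquisition.

## The simulator and what it does (not) emulate

Every stage is testable without microscopy data through a ground-truthed
simulator. Its defaults mirror the targeted acquisition regime: 250 frames
at 5 Hz (spatial resolution is configurable; tests use fields of 96–190 px
so suites run in seconds — the method itself is resolution-agnostic).
Cells are flat disks with a 1-px cosine rim (compact somata at low
magnification), placed by rejection sampling at a minimum spacing of 2.5x
radius, or as tight pairs at 1.2x radius when `clustered = TRUE` to
exercise watershed splitting. Firing is either independent Poisson trains
per cell (immature, unsynchronized cultures) or shared Poisson burst times
that each cell joins with a participation probability, plus background
events (matured, network-bursting cultures). Each event contributes a
peak-normalized double-exponential transient
`A (1 - e^{-t/tau_r}) e^{-t/tau_d}`; the defaults `tau_r = 0.1` s and
`tau_d = 0.7` s are on the scale of a fast indicator — only their ratio to
the frame interval matters for the tests. Pixel values are
`baseline (1 + gradient) + disk * baseline * dF`, optionally
Poisson-resampled (shot noise) with additive Gaussian read noise, clipped
to 16 bits.

The simulator deliberately omits photobleaching (minimized experimentally
in the targeted regime), neuropil and dendritic signal, cell overlap in
depth, motion, and indicator saturation. Passing recovery tests therefore
demonstrates the pipeline's correctness on compact, well-isolated somata
with stationary baselines — not robustness to bleaching drift or dense
tissue.

Three presets encode the qualitative regimes the pipeline must
discriminate: `immature_control` (asynchronous, low amplitude 0.4),
`mature_control` (network bursts, participation 0.75, amplitude 1.0), and
`cytokine_like` (network bursts, participation 0.95, amplitude 1.5 —
inflammatory-cytokine-treated young cultures show exactly this direction:
higher amplitude and synchrony than vehicle). These comparisons are
direction-of-effect only; no hypothesis testing is attempted or implied.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `saturated_fraction` | 0.0035 | common 0.35% contrast-stretch convention |
| `threshold_method` | isodata | the ImageJ "Default" intermeans family; otsu/fixed available |
| `outlier_radius`, `outlier_delta` | 2 px, 50 | typical despeckle settings for 8-bit input |
| `morph_iterations` | 1 | one erode + one dilate (3x3 cross), listed order |
| `min_area`, `max_area` | 30, 1500 px² | soma-scale limits at ~10x; exposed because published limits vary |
| `n_bins` (state levels) | 100 | robust from 250 to several thousand samples |
| reference fractions | 0.1/0.5/0.9 | the standard bilevel (IEEE-181-style) convention |
| synchrony threshold | 0.15 dF | excludes baseline fluctuations from correlation |

## Numerical choices and edge cases

* **8-bit conversion** maps `[min, max]` to `[0, 255]` with
  round-half-away-from-zero; a constant image maps to zero. Because the
  map is affine-invariant, segmentation is unchanged by intensity offsets
  or gain.
* **Contrast stretch** clips `floor(n * f / 2)` pixels per tail; with
  `f = 0` it degenerates to a min–max stretch; constant images pass
  through.
* **Otsu plateau**: between-class variance is flat across an empty
  histogram gap, so the plateau midpoint is used (average of maximizing
  thresholds), not its first edge.
* **Outlier removal** is a conditional sliding median (reflected edges):
  a pixel is replaced only when it exceeds its neighborhood median by
  `delta`. On binary masks the effective `delta` is 0.5 — isolated salt
  is removed; note that the extreme corner pixels of large square blobs
  are a minority of their window and are trimmed too, as with any median
  filter.
* **Watershed** runs on the distance transform with flooding tolerance
  1 px (suppresses splits from rim roughness); pixels where two basins
  meet are reassigned to background so touching blobs end up as distinct
  components under 8-connectivity.
* **Particle labels** are assigned in raster-scan order of each
  component's first pixel and renumbered consecutively after size
  filtering; coordinates are 0-based `(row, col)`, bounding boxes
  half-open.
* **State levels** sit at histogram bin centers, so a clean unit-amplitude
  square wave reports amplitude `1 - 1/n_bins`; analytic fixtures are
  asserted to within one bin plus one sample.
* **Crossing times** are linearly interpolated; a sample exactly at a
  reference level counts as crossed at that sample. Leading falls and
  trailing rises (incomplete pulses) are discarded. Pulses missing a 10%
  or 90% crossing inside the record carry `NA` rise/fall values, which
  propagate as missing — never as zero — into per-ROI means.
* **Frequency** is the reciprocal of the mean period, not the mean of
  reciprocal periods; it (and duty cycle) requires at least two pulses,
  amplitude and width at least one. ROIs with `F_min <= 0` or zero
  variance after thresholding are excluded and flagged, never imputed.
* **Sampling adequacy**: rise-time and width estimates need the rise to
  span at least ~2–3 samples; with a 0.1 s rise at 5 Hz the sampled peak
  (hence the high state level) fluctuates between transients. Recovery
  tests therefore use kinetics with `frame_rate * rise_tau >= 3`; the
  same consideration applies to real acquisitions.

## Design decisions taken where the method was open

* "Amplitude" is defined as the state-level span; the mean per-pulse peak
  is also emitted (`peak_mean`) since either reading is defensible.
* Multi-pulse features aggregate by arithmetic mean per ROI.
* Thresholding for synchrony zeroes sub-threshold samples rather than
  deleting frames, keeping all pairs on a common time base; a binarized
  variant (`binarize = TRUE`) correlates supra-threshold indicators.
* The activity score that orders raster rows (sum of supra-threshold dF)
  reuses the synchrony threshold for consistency.
* Trace extraction uses the per-frame mean (not sum) of ROI pixels.
* Background normalization is realized by the contrast stretch plus
  outlier removal; no separate background-subtraction stage is exposed.
* The per-movie seed drives one root generator from which per-cell and
  per-stage sub-streams are derived, so any simulated object is
  reproducible from its config alone.

## Problem sizes used in the shipped tests

Unit and acceptance tests simulate fields of 10–30 cells on 64–190 px
grids, 100–600 frames at 5–10 Hz, 120 random traces for the
oracle-equivalence check, and 5-point sweeps for frequency/decay
recovery. These sizes keep the full suite under a minute while leaving
every statistical margin (Poisson counts, correlation nulls) wide enough
to be stable across seeds.

## Known limitations

* The segmentation chain shares the MIP approach's blindness to neurons
  that never fire during the acquisition.
* Bilevel analysis assumes a (noisily) two-state trace; cells with
  strongly graded or drifting baselines violate the histogram-mode
  assumption and are best handled upstream (e.g., detrending, which the
  package does not provide).
* Pearson synchrony is a linear, zero-lag measure; delayed or nonlinear
  coupling is invisible to it.
* CV summaries require positive means; the signed negative slew rate is
  reported but its CV is undefined under this convention.
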