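# calciwave

Automated analysis of calcium-imaging movies from neuronal cultures:
ROI segmentation, ΔF/F trace extraction, time-domain bilevel waveform
features, and network-synchrony statistics — plus a ground-truthed
synthetic-movie simulator so the whole chain is testable without
microscopy data.

## The problem

High-density cortical cultures expressing a fast calcium indicator
(GCaMP6f-class) report neuronal activity as fluorescence transients: a
fast rise on depolarization and a slower exponential decay as calcium is
sequestered. As such networks mature they shift from unsynchronized
single-cell oscillations to regular population bursts. Quantifying that
shift — per neuron and per network, across hundreds of cells and many
fields — requires an automated pipeline from raw `T × H × W` movie to a
table of waveform and synchrony descriptors. calciwave implements that
pipeline for R.

## The method

1. **Segmentation** (`segment()`): maximum-intensity projection → 8-bit →
   percentile contrast stretch → isodata threshold → sliding-median
   despeckle → morphological opening (3×3 cross) → distance-transform
   watershed → size-limited particle analysis ([30, 1500] px² by default).
   Every stage is exported individually.
2. **Traces** (`extract_traces()`, `normalize_dff()`): per-ROI mean
   fluorescence, normalized as ΔF = (F − F_min)/F_min with F_min the
   per-ROI minimum over the acquisition; min(ΔF) = 0 exactly and ΔF is
   gain-invariant.
3. **Waveform features** (`extract_features()`, `features_table()`):
   bilevel state levels from the amplitude histogram; pulses from
   interpolated 50%-reference crossings; per ROI, the seven descriptors

   | feature | definition |
   |---|---|
   | amplitude | high − low state level (ΔF) |
   | pulse width | mean 50%→50% duration (s) |
   | frequency | 1 / mean inter-burst interval (Hz) |
   | rise / fall time | 10%→90% (90%→10%) crossing interval (s) |
   | slew rates | 10–90% span / rise or fall time (ΔF/s) |
   | duty cycle | mean width / mean period |

4. **Synchrony** (`synchrony()`): traces thresholded at ΔF > 0.15 to
   exclude baseline fluctuations, pairwise Pearson matrix over frames,
   per-neuron mean correlation across all pairings.
   `coefficient_of_variation()` / `cv_report()` summarize variability
   across fields, serial acquisitions, and ROIs.

`run_pipeline()` orchestrates all stages and writes CSV tables, a raster
PNG of the most active ROIs, and a JSON run report. A thin CLI over the
same functions ships in `inst/cli/calciwave.R`
(`simulate | run | segment | extract | features | synchrony | raster |
compare`).

## Worked example

```r
library(calciwave)

cfg <- condition_preset("mature_control", seed = 42)  # network bursts
sim <- simulate_movie(cfg)
sim$movie
#> <cal_movie> 250 frames of 160 x 160 px at 5 Hz (50.0 s)

rois <- segment(sim$movie)
rois
#> <cal_roiset> 30 ROI(s) on a 160 x 160 px grid (8-connectivity)
#>   area: 30-90 px^2 (median 55.5)

tr <- normalize_dff(extract_traces(sim$movie, rois), 5, rois$table$label)
ft <- features_table(tr)
round(attr(ft, "field_means"), 3)
#>     amplitude pulse_width_s  frequency_hz   rise_time_s   fall_time_s
#>         0.773         1.000         0.173         0.521         1.705
#>      slew_pos      slew_neg    duty_cycle     peak_mean
#>         3.981        -0.389         0.174         1.055

synchrony(tr)
#> <cal_synchrony> 30 ROI(s), threshold dF > 0.15
#>   mean pairwise r: median 0.590 (range 0.266 to 0.757)
```

All 30 simulated somata are recovered as ROIs; the field-mean amplitude
(~0.77 ΔF) reflects the preset's event amplitude (1.0) minus histogram
quantization and sub-sampling of fast rises; the ~0.17 Hz frequency is
the network's inter-burst rate; and the high median pairwise r (0.59)
is the expected signature of the bursting regime (the asynchronous
`immature_control` preset yields r near 0).

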