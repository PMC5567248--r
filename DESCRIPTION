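Package: calciwave
Title: Automated Calcium-Imaging Segmentation, Trace Extraction, and
    Waveform Analysis for Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated high-content analysis pipeline for GCaMP
    fluorescence time-series movies of cultured neurons: ImageJ-macro-style
    region-of-interest (ROI) segmentation (maximum-intensity projection,
    8-bit conversion, contrast enhancement, isodata thresholding, outlier
    removal, morphological opening, distance-transform watershed, and
    size-limited particle analysis), per-ROI dF/F trace extraction
    normalized to the minimum fluorescence, time-domain bilevel waveform
    feature extraction (amplitude, pulse width, frequency, rise and fall
    time, slew rates, duty cycle), network-synchrony statistics via
    thresholded pairwise Pearson correlation, and coefficient-of-variation
    summaries across fields, acquisitions, and ROIs. A ground-truthed
    synthetic-movie simulator emulating somatic calcium transients and
    asynchronous versus network-burst firing regimes makes every stage
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
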