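# Per-ROI fluorescence extraction and dF/F_min normalization.

#' Extract raw per-ROI fluorescence traces
#'
#' `raw_F[k, t]` is the arithmetic mean of frame `t` over the pixels of ROI
#' label `k`.
#'
#' @param movie a [cal_movie()] sharing the ROI set's spatial grid.
#' @param rois a `cal_roiset` from [segment()] / [analyze_particles()].
#' @return numeric matrix, ROIs x frames, rows ordered by ascending label
#'   (rownames `roi_<label>`).
#' @export
extract_traces <- function(movie, rois) {
  data <- movie$data
  d <- dim(data)
  lab <- rois$label_image
  if (d[2] != nrow(lab) || d[3] != ncol(lab))
    stop("movie and label image dimensions disagree")
  K <- nrow(rois$table)
  T_ <- d[1]
  raw <- matrix(0, K, T_)
  if (K == 0) return(raw)
  fg <- which(lab > 0)
  labv <- lab[fg]
  counts <- tabulate(labv, nbins = K)
  for (t in seq_len(T_)) {
    fr <- data[t, , ]
    raw[, t] <- rowsum(fr[fg], labv)[, 1] / counts
  }
  rownames(raw) <- paste0("roi_", rois$table$label)
  raw
}

#' Normalize traces to dF = (F - F_min) / F_min
#'
#' `F_min` is the exact per-ROI minimum over the acquisition (optionally a
#' low percentile to guard single-frame dropouts). ROIs whose baseline is
#' not positive cannot be normalized; they are excluded with a warning and
#' their labels reported.
#'
#' @param raw_F ROIs x frames matrix from [extract_traces()].
#' @param frame_rate Hz, stored alongside the traces.
#' @param roi_labels integer labels matching the rows of `raw_F`.
#' @param baseline_percentile percentile (0-100) used for `F_min`; the
#'   default 0 is the exact minimum.
#' @return a `cal_traces` object: `raw_F`, `dff`, `f_min`, `frame_rate`,
#'   `roi_labels`, `excluded` (labels dropped for `F_min <= 0`). Each kept
#'   row of `dff` has minimum exactly 0 when `baseline_percentile = 0`.
#' @export
normalize_dff <- function(raw_F, frame_rate = 5,
                          roi_labels = seq_len(nrow(raw_F)),
                          baseline_percentile = 0) {
  stopifnot(is.matrix(raw_F))
  f_min <- if (baseline_percentile <= 0) apply(raw_F, 1, min)
           else apply(raw_F, 1, stats::quantile,
                      probs = baseline_percentile / 100, names = FALSE)
  bad <- f_min <= 0
  if (any(bad))
    warning(sprintf("%d ROI(s) excluded: F_min <= 0 (labels %s)", sum(bad),
                    paste(roi_labels[bad], collapse = ", ")))
  keep <- !bad
  dff <- sweep(raw_F[keep, , drop = FALSE], 1, f_min[keep], "-")
  dff <- sweep(dff, 1, f_min[keep], "/")
  structure(list(raw_F = raw_F[keep, , drop = FALSE], dff = dff,
                 f_min = f_min[keep], frame_rate = frame_rate,
                 roi_labels = roi_labels[keep],
                 excluded = roi_labels[bad]),
            class = "cal_traces")
}

#' Rank ROIs by activity
#'
#' Activity score = sum over frames of dF values strictly above the
#' threshold (the same cut used to exclude baseline fluctuations in the
#' synchrony analysis). ROIs are ordered by descending score with ties
#' broken by ascending label — the ordering used to pick the "most active"
#' ROIs for raster display.
#'
#' @param traces a `cal_traces` (or a bare dF matrix).
#' @param threshold dF cut; default 0.15.
#' @return integer vector of row indices into the dF matrix, most active
#'   first.
#' @export
rank_activity <- function(traces, threshold = 0.15) {
  dff <- if (inherits(traces, "cal_traces")) traces$dff else traces
  labels <- if (inherits(traces, "cal_traces")) traces$roi_labels
            else seq_len(nrow(dff))
  score <- rowSums(dff * (dff > threshold))
  order(-score, labels)
}
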