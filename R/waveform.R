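# Time-domain bilevel waveform analysis of dF traces: state-level
# estimation from the amplitude histogram, reference-level crossing search
# with linear interpolation, and the per-ROI burst parameters (amplitude,
# pulse width, frequency, rise/fall time, slew rates, duty cycle).

#' Estimate bilevel state levels from the amplitude histogram
#'
#' The trace's values are histogrammed over `[min, max]` with `n_bins`
#' equal-width bins; the low state level is the modal bin center of the
#' lower half of the bins and the high state level the modal bin center of
#' the upper half (ties resolved to the first bin). This is the standard
#' histogram-mode convention for two-state signals.
#'
#' @param trace numeric vector, length >= 4, non-constant.
#' @param n_bins histogram bins; default 100.
#' @return a `state_levels` list: `low`, `high`, `n_bins`, `bin_width`.
#' @export
estimate_state_levels <- function(trace, n_bins = 100) {
  if (length(trace) < 4) stop("trace must contain at least 4 samples")
  lo <- min(trace); hi <- max(trace)
  if (hi == lo) stop("constant trace: state levels undefined")
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  # right-closed bins, values at lo fall in bin 1
  bin <- pmin(pmax(findInterval(trace, breaks, rightmost.closed = TRUE),
                   1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  half <- floor(n_bins / 2)
  low_idx <- which.max(counts[seq_len(half)])
  high_idx <- half + which.max(counts[(half + 1):n_bins])
  structure(list(low = centers[low_idx], high = centers[high_idx],
                 n_bins = n_bins, bin_width = diff(breaks)[1]),
            class = "state_levels")
}

# All upward (pos) or downward (neg) crossing times of `ref`, linearly
# interpolated between samples. Tie rule: a sample exactly at the reference
# level counts as having crossed on that sample.
crossing_times <- function(x, t, ref, direction) {
  n <- length(x)
  if (n < 2) return(numeric(0))
  i <- seq_len(n - 1)
  if (direction == "pos") hit <- x[i] < ref & x[i + 1] >= ref
  else hit <- x[i] > ref & x[i + 1] <= ref
  i <- i[hit]
  if (!length(i)) return(numeric(0))
  t[i] + (ref - x[i]) / (x[i + 1] - x[i]) * (t[i + 1] - t[i])
}

#' Find complete pulses via reference-level crossings
#'
#' Reference levels at `mid_fraction` (default 50\%), `lower_ref_fraction`
#' (10\%) and `upper_ref_fraction` (90\%) of the span between the state
#' levels. A pulse is a consecutive (positive-going, negative-going) pair of
#' mid-reference crossings; a leading negative-going or trailing
#' positive-going crossing belongs to an incomplete pulse and is discarded.
#' Rise time is measured between the lower- and upper-reference crossings
#' bracketing the positive mid crossing, fall time symmetrically on the
#' negative transition; positive slew rate is the reference span
#' (`0.8 x amplitude` at the default fractions) divided by the rise time,
#' and the negative slew rate is the same span divided by the fall time with
#' negative sign. All crossing times are linearly interpolated.
#'
#' @param trace numeric dF vector.
#' @param frame_rate Hz; sample `i` is at time `(i - 1) / frame_rate`.
#' @param levels a `state_levels` from [estimate_state_levels()].
#' @param mid_fraction,lower_ref_fraction,upper_ref_fraction reference
#'   fractions of the state-level span, ordered
#'   `0 < lower < mid <= upper < 1`.
#' @return data frame with one row per complete pulse: `t_rise_mid`,
#'   `t_fall_mid`, `width`, `rise_time`, `fall_time`, `slew_pos`,
#'   `slew_neg`, `peak` (sample maximum within the pulse). Rise/fall times
#'   are `NA` when the corresponding reference crossings are clipped by the
#'   trace boundary.
#' @export
find_pulses <- function(trace, frame_rate, levels,
                        mid_fraction = 0.5, lower_ref_fraction = 0.1,
                        upper_ref_fraction = 0.9) {
  stopifnot(inherits(levels, "state_levels"),
            lower_ref_fraction > 0, lower_ref_fraction < mid_fraction,
            mid_fraction <= upper_ref_fraction, upper_ref_fraction < 1)
  span <- levels$high - levels$low
  mid <- levels$low + mid_fraction * span
  lo_ref <- levels$low + lower_ref_fraction * span
  up_ref <- levels$low + upper_ref_fraction * span
  tt <- (seq_along(trace) - 1) / frame_rate

  pos_mid <- crossing_times(trace, tt, mid, "pos")
  neg_mid <- crossing_times(trace, tt, mid, "neg")
  empty <- data.frame(t_rise_mid = numeric(0), t_fall_mid = numeric(0),
                      width = numeric(0), rise_time = numeric(0),
                      fall_time = numeric(0), slew_pos = numeric(0),
                      slew_neg = numeric(0), peak = numeric(0))
  if (!length(pos_mid) || !length(neg_mid)) return(empty)
  neg_mid <- neg_mid[neg_mid > pos_mid[1]]          # drop leading falls
  if (!length(neg_mid)) return(empty)

  pos_lo <- crossing_times(trace, tt, lo_ref, "pos")
  pos_up <- crossing_times(trace, tt, up_ref, "pos")
  neg_up <- crossing_times(trace, tt, up_ref, "neg")
  neg_lo <- crossing_times(trace, tt, lo_ref, "neg")

  pulses <- empty
  j <- 1L
  for (tp in pos_mid) {
    # next falling mid crossing after this rising one, unclaimed
    tn <- neg_mid[neg_mid > tp]
    if (!length(tn)) break                          # trailing incomplete
    tn <- tn[1]
    if (nrow(pulses) && tn <= pulses$t_fall_mid[nrow(pulses)]) next
    if (nrow(pulses) && tp <= pulses$t_fall_mid[nrow(pulses)]) next
    lo_before <- pos_lo[pos_lo <= tp]
    up_after <- pos_up[pos_up >= tp]
    rise <- if (length(lo_before) && length(up_after))
      min(up_after) - max(lo_before) else NA_real_
    up_before <- neg_up[neg_up <= tn]
    lo_after <- neg_lo[neg_lo >= tn]
    fall <- if (length(up_before) && length(lo_after))
      min(lo_after) - max(up_before) else NA_real_
    ref_span <- up_ref - lo_ref
    in_pulse <- tt >= tp & tt <= tn
    pulses <- rbind(pulses, data.frame(
      t_rise_mid = tp, t_fall_mid = tn, width = tn - tp,
      rise_time = rise, fall_time = fall,
      slew_pos = if (is.na(rise) || rise <= 0) NA_real_ else ref_span / rise,
      slew_neg = if (is.na(fall) || fall <= 0) NA_real_ else -ref_span / fall,
      peak = if (any(in_pulse)) max(trace[in_pulse]) else max(trace)))
  }
  pulses
}

#' Extract waveform features from one dF trace
#'
#' Amplitude is the state-level span (high - low). Pulse width, rise/fall
#' time and slew rates are arithmetic means over complete pulses (missing
#' per-pulse values are dropped, never zero-filled). The period is the
#' difference between successive positive-going mid-reference crossings;
#' frequency is the reciprocal of the *mean* period (the inverse of the
#' mean inter-burst interval) and duty cycle is mean width / mean period.
#' A trace with no complete pulse (or a constant trace) is marked invalid
#' with all features `NA`; frequency and duty cycle additionally require at
#' least two pulses.
#'
#' @param trace numeric dF vector, length >= 4.
#' @param frame_rate Hz.
#' @param n_bins state-level histogram bins.
#' @param mid_fraction,lower_ref_fraction,upper_ref_fraction see
#'   [find_pulses()].
#' @return one-row data frame: `n_pulses`, `amplitude`, `pulse_width_s`,
#'   `frequency_hz`, `rise_time_s`, `fall_time_s`, `slew_pos`, `slew_neg`,
#'   `duty_cycle`, `peak_mean` (auxiliary mean per-pulse peak), `valid`.
#' @export
extract_features <- function(trace, frame_rate, n_bins = 100,
                             mid_fraction = 0.5, lower_ref_fraction = 0.1,
                             upper_ref_fraction = 0.9) {
  invalid <- data.frame(n_pulses = 0L, amplitude = NA_real_,
                        pulse_width_s = NA_real_, frequency_hz = NA_real_,
                        rise_time_s = NA_real_, fall_time_s = NA_real_,
                        slew_pos = NA_real_, slew_neg = NA_real_,
                        duty_cycle = NA_real_, peak_mean = NA_real_,
                        valid = FALSE)
  if (length(trace) < 4) stop("trace must contain at least 4 samples")
  if (max(trace) == min(trace)) return(invalid)
  levels <- estimate_state_levels(trace, n_bins)
  pulses <- find_pulses(trace, frame_rate, levels, mid_fraction,
                        lower_ref_fraction, upper_ref_fraction)
  n <- nrow(pulses)
  if (n == 0) return(invalid)
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  periods <- diff(pulses$t_rise_mid)
  freq <- if (n >= 2) 1 / mean(periods) else NA_real_
  duty <- if (n >= 2) mean(pulses$width) / mean(periods) else NA_real_
  data.frame(n_pulses = n, amplitude = levels$high - levels$low,
             pulse_width_s = mean(pulses$width), frequency_hz = freq,
             rise_time_s = mean_na(pulses$rise_time),
             fall_time_s = mean_na(pulses$fall_time),
             slew_pos = mean_na(pulses$slew_pos),
             slew_neg = mean_na(pulses$slew_neg),
             duty_cycle = duty, peak_mean = mean_na(pulses$peak),
             valid = TRUE)
}

#' Per-ROI waveform feature table
#'
#' Applies [extract_features()] to every row of a trace matrix and attaches
#' field-level means (over valid ROIs, per feature, `NA`s dropped) as the
#' `"field_means"` attribute.
#'
#' @param traces a `cal_traces` (or bare dF matrix).
#' @param frame_rate Hz; taken from `traces` when it is a `cal_traces`.
#' @param ... passed to [extract_features()].
#' @return data frame with a leading `roi` column, one row per ROI.
#' @export
features_table <- function(traces, frame_rate = NULL, ...) {
  dff <- if (inherits(traces, "cal_traces")) traces$dff else traces
  labels <- if (inherits(traces, "cal_traces")) traces$roi_labels
            else seq_len(nrow(dff))
  if (is.null(frame_rate)) {
    if (!inherits(traces, "cal_traces"))
      stop("'frame_rate' required for a bare matrix")
    frame_rate <- traces$frame_rate
  }
  rows <- lapply(seq_len(nrow(dff)), function(k)
    cbind(roi = labels[k], extract_features(dff[k, ], frame_rate, ...)))
  tab <- if (length(rows)) do.call(rbind, rows)
    else cbind(roi = integer(0),
               extract_features(c(0, 0, 1, 0), 1)[0, ])
  feat_cols <- c("amplitude", "pulse_width_s", "frequency_hz", "rise_time_s",
                 "fall_time_s", "slew_pos", "slew_neg", "duty_cycle",
                 "peak_mean")
  valid <- tab$valid %in% TRUE
  means <- vapply(feat_cols, function(cn) {
    v <- tab[[cn]][valid]
    if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  attr(tab, "field_means") <- means
  tab
}
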