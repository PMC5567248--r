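# Network synchrony via thresholded pairwise Pearson correlation, and
# coefficient-of-variation summaries across fields, serial acquisitions,
# and ROIs.

#' Threshold dF traces to exclude baseline fluctuations
#'
#' Values at or below the threshold are set to 0; supra-threshold values
#' are kept unchanged (all traces stay on the common time base).
#'
#' @param dff ROIs x frames dF matrix (or vector).
#' @param threshold dF cut, >= 0; default 0.15.
#' @return matrix/vector of the same shape.
#' @export
threshold_traces <- function(dff, threshold = 0.15) {
  if (threshold < 0) stop("'threshold' must be non-negative")
  dff * (dff > threshold)
}

#' Pairwise Pearson correlation matrix of thresholded traces
#'
#' Standard sample Pearson r for every ROI pair over all frames. Rows with
#' zero variance after thresholding (silent cells) carry no correlation
#' information and are excluded, not imputed.
#'
#' @param th ROIs x frames matrix (already thresholded).
#' @param roi_labels labels for the rows.
#' @return list with `corr_matrix` (kept ROIs, dimnames = labels),
#'   `kept` and `excluded` label vectors.
#' @export
pearson_matrix <- function(th, roi_labels = seq_len(nrow(th))) {
  v <- apply(th, 1, stats::var)
  keep <- v > 0
  if (sum(keep) < 2)
    stop("fewer than 2 ROIs with non-zero variance: synchrony undefined")
  cm <- stats::cor(t(th[keep, , drop = FALSE]))
  dimnames(cm) <- list(roi_labels[keep], roi_labels[keep])
  list(corr_matrix = cm, kept = roi_labels[keep],
       excluded = roi_labels[!keep])
}

#' Per-ROI mean pairwise correlation
#'
#' Mean of each row of the correlation matrix excluding the unit diagonal:
#' the average Pearson correlation of a given neuron across all pairings.
#'
#' @param corr_matrix square symmetric correlation matrix.
#' @return named numeric vector of per-ROI means.
#' @export
mean_pairwise_r <- function(corr_matrix) {
  n <- nrow(corr_matrix)
  if (n < 2) stop("need at least a 2 x 2 correlation matrix")
  (rowSums(corr_matrix) - diag(corr_matrix)) / (n - 1)
}

#' Network synchrony of a trace set
#'
#' Thresholds the dF traces ([threshold_traces()]), computes the pairwise
#' Pearson matrix ([pearson_matrix()]) and per-ROI mean correlations
#' ([mean_pairwise_r()]).
#'
#' @param traces a `cal_traces` (or bare dF matrix).
#' @param threshold dF cut; default 0.15.
#' @param binarize if `TRUE`, correlate 0/1 supra-threshold indicators
#'   instead of thresholded-continuous values.
#' @return a `cal_synchrony` object: `threshold`, `corr_matrix`, `mean_r`
#'   (named by ROI label), `excluded_rois`.
#' @export
synchrony <- function(traces, threshold = 0.15, binarize = FALSE) {
  dff <- if (inherits(traces, "cal_traces")) traces$dff else traces
  labels <- if (inherits(traces, "cal_traces")) traces$roi_labels
            else seq_len(nrow(dff))
  th <- threshold_traces(dff, threshold)
  if (binarize) th <- (th > 0) * 1
  pm <- pearson_matrix(th, labels)
  structure(list(threshold = threshold, corr_matrix = pm$corr_matrix,
                 mean_r = mean_pairwise_r(pm$corr_matrix),
                 excluded_rois = pm$excluded),
            class = "cal_synchrony")
}

#' Coefficient of variation, percent
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, times
#' 100. Requires at least two values; undefined (NA with a warning) when
#' the mean is not positive.
#'
#' @param values numeric vector, length >= 2.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m <= 0) {
    warning("CV undefined for non-positive mean")
    return(NA_real_)
  }
  stats::sd(values) / m * 100
}

#' CV report across fields, acquisitions, or ROIs
#'
#' * `spatial` — CV of field-mean features across multiple optical fields.
#' * `temporal` — CV of field-mean features across serial acquisitions of
#'   one field.
#' * `inter_roi` — CV across ROI-level features within one acquisition.
#'
#' For the grouped scopes pass one feature table (from [features_table()])
#' per field/acquisition; field means are taken over valid ROIs. For
#' `inter_roi` pass a single table (or a list of length 1).
#'
#' @param tables a feature table or list of feature tables.
#' @param scope `"spatial"`, `"temporal"`, or `"inter_roi"`.
#' @param parameters feature columns to summarize.
#' @return tidy data frame: `scope`, `parameter`, `cv_percent`, `n_units`.
#' @export
cv_report <- function(tables,
                      scope = c("spatial", "temporal", "inter_roi"),
                      parameters = c("amplitude", "pulse_width_s",
                                     "frequency_hz", "rise_time_s",
                                     "fall_time_s", "slew_pos", "slew_neg",
                                     "duty_cycle")) {
  scope <- match.arg(scope)
  if (is.data.frame(tables)) tables <- list(tables)
  cv_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) <= 0) NA_real_
    else stats::sd(x) / mean(x) * 100
  }
  if (scope == "inter_roi") {
    if (length(tables) != 1)
      stop("inter_roi scope expects a single acquisition's table")
    tab <- tables[[1]]
    tab <- tab[tab$valid %in% TRUE, , drop = FALSE]
    res <- data.frame(scope = scope, parameter = parameters,
                      cv_percent = vapply(parameters,
                                          function(p) cv_of(tab[[p]]),
                                          numeric(1)),
                      n_units = nrow(tab), row.names = NULL)
    return(res)
  }
  if (length(tables) < 2)
    stop(sprintf("%s scope requires at least 2 groups", scope))
  means <- vapply(parameters, function(p) {
    vapply(tables, function(tab) {
      v <- tab[[p]][tab$valid %in% TRUE]
      if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(tables)))
  data.frame(scope = scope, parameter = parameters,
             cv_percent = apply(means, 2, cv_of),
             n_units = length(tables), row.names = NULL)
}
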