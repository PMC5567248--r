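# Readers/writers for the pipeline's on-disk formats: multi-page 16-bit
# TIFF movies and label images, trace CSVs with a JSON metadata sidecar,
# ROI tables, ground truth, and configs.

#' Write a movie as a multi-page 16-bit TIFF
#'
#' One page per frame; intensities are stored as 16-bit unsigned values.
#'
#' @param movie a [cal_movie()] with integer counts in `[0, 65535]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  pages <- lapply(seq_len(dim(movie$data)[1]),
                  function(t) movie$data[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file with one page per frame.
#' @param frame_rate acquisition rate in Hz to attach.
#' @return a [cal_movie()].
#' @export
read_movie_tiff <- function(path, frame_rate = 5) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  data <- array(0, dim = c(length(pages), H, W))
  for (t in seq_along(pages)) data[t, , ] <- pages[[t]]
  cal_movie(data, frame_rate)
}

#' Write a label image as 16-bit TIFF
#' @param rois a `cal_roiset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(rois, path) {
  tiff::writeTIFF(rois$label_image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write traces as CSV plus JSON metadata sidecar
#'
#' The CSV has one row per frame: a leading `time_s` column, then one
#' `roi_<label>` column per ROI. The sidecar (`<path>.meta.json`) records
#' frame rate and per-ROI `F_min`.
#'
#' @param traces a `cal_traces`.
#' @param path CSV output file.
#' @param what `"dff"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, what = c("dff", "raw")) {
  what <- match.arg(what)
  m <- if (what == "dff") traces$dff else traces$raw_F
  df <- data.frame(time_s = (seq_len(ncol(m)) - 1) / traces$frame_rate)
  for (i in seq_len(nrow(m))) df[[paste0("roi_", traces$roi_labels[i])]] <- m[i, ]
  utils::write.csv(df, path, row.names = FALSE)
  nm <- if (length(traces$roi_labels))
    paste0("roi_", traces$roi_labels) else character(0)
  meta <- list(frame_rate = traces$frame_rate,
               roi_labels = traces$roi_labels,
               f_min = as.list(stats::setNames(traces$f_min, nm)),
               excluded = traces$excluded, what = what)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace CSV written by [write_traces_csv()]
#'
#' @param path CSV file; the `<path>.meta.json` sidecar is read when
#'   present, otherwise the frame rate is inferred from `time_s`.
#' @return a `cal_traces` (with `raw_F` equal to the stored matrix when the
#'   sidecar marks it raw; `dff` is then recomputed, otherwise the stored
#'   matrix is taken as dF directly).
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  roi_cols <- grep("^roi_", names(df), value = TRUE)
  m <- t(as.matrix(df[roi_cols]))
  labels <- as.integer(sub("^roi_", "", roi_cols))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    frame_rate <- meta$frame_rate
    what <- if (!is.null(meta$what)) meta$what else "dff"
  } else {
    dt <- diff(df$time_s)
    frame_rate <- 1 / mean(dt)
    what <- "dff"
  }
  if (what == "raw") return(normalize_dff(m, frame_rate, labels))
  structure(list(raw_F = NULL, dff = m,
                 f_min = rep(NA_real_, nrow(m)), frame_rate = frame_rate,
                 roi_labels = labels, excluded = integer(0)),
            class = "cal_traces")
}

#' Write ROI table as CSV
#' @param rois a `cal_roiset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(rois, path) {
  utils::write.csv(rois$table, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON (+ true-trace CSV)
#'
#' @param truth ground truth from [simulate_movie()].
#' @param json_path JSON output (centers, radii, event times, label).
#' @param traces_csv optional CSV of true dF traces: one row per frame, one
#'   column per cell, header row.
#' @return `json_path`, invisibly.
#' @export
write_ground_truth <- function(truth, json_path, traces_csv = NULL) {
  meta <- list(cell_centers = truth$cell_centers,
               cell_radii = truth$cell_radii,
               event_times = truth$event_times,
               burst_times = truth$burst_times,
               condition_label = truth$condition_label)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(traces_csv)) {
    m <- t(truth$true_traces)
    colnames(m) <- paste0("cell_", seq_len(ncol(m)))
    utils::write.csv(as.data.frame(m), traces_csv, row.names = FALSE)
  }
  invisible(json_path)
}

#' Write a simulation config as YAML
#' @param config a [sim_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}
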