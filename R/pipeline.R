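# End-to-end orchestration: segment -> extract/normalize -> waveform
# features -> synchrony, with CSV/JSON/PNG reporting.

#' Run the full analysis pipeline
#'
#' Executes segmentation, trace extraction and dF normalization, waveform
#' feature extraction, and synchrony analysis in order, writing every
#' result table plus a JSON run report to `output_dir`. Deterministic for a
#' fixed input and configuration.
#'
#' @param input a [cal_movie()], a path to a multi-page TIFF movie, or a
#'   path to a trace CSV (imaging stages skipped).
#' @param output_dir directory for outputs (created if missing).
#' @param seg a [seg_config()].
#' @param frame_rate Hz, used when `input` is a TIFF path.
#' @param synchrony_threshold dF cut for the Pearson analysis; default 0.15.
#' @param n_bins,mid_fraction,lower_ref_fraction,upper_ref_fraction waveform
#'   settings, see [extract_features()].
#' @param max_raster_rois ROIs shown in the raster (most active first).
#' @param debug if `TRUE`, writes intermediate segmentation images as TIFF.
#' @return (invisibly) list with `rois`, `traces`, `features`, `synchrony`
#'   (NULL when undefined), and `report`.
#' @export
run_pipeline <- function(input, output_dir, seg = seg_config(),
                         frame_rate = 5, synchrony_threshold = 0.15,
                         n_bins = 100, mid_fraction = 0.5,
                         lower_ref_fraction = 0.1, upper_ref_fraction = 0.9,
                         max_raster_rois = 100, debug = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  rois <- NULL
  if (inherits(input, "cal_movie") ||
      (is.character(input) && grepl("\\.tiff?$", input, ignore.case = TRUE))) {
    movie <- if (inherits(input, "cal_movie")) input
             else read_movie_tiff(input, frame_rate)
    rois <- segment(movie, seg, keep_intermediates = debug)
    tick("segment")
    write_roi_csv(rois, file.path(output_dir, "rois.csv"))
    write_label_tiff(rois, file.path(output_dir, "labels.tiff"))
    if (debug) {
      im <- attr(rois, "intermediates")
      for (nm in c("mip", "img8", "enhanced", "mask", "cleaned", "opened",
                   "split")) {
        x <- im[[nm]]
        tiff::writeTIFF(x / max(1, max(x)),
                        file.path(output_dir, paste0("debug_", nm, ".tiff")))
      }
    }
    if (nrow(rois$table) == 0) {
      warning("no ROIs found; emitting empty tables")
      traces <- structure(list(raw_F = matrix(0, 0, dim(movie$data)[1]),
                               dff = matrix(0, 0, dim(movie$data)[1]),
                               f_min = numeric(0),
                               frame_rate = movie$frame_rate,
                               roi_labels = integer(0),
                               excluded = integer(0)),
                          class = "cal_traces")
    } else {
      raw <- extract_traces(movie, rois)
      traces <- normalize_dff(raw, movie$frame_rate, rois$table$label)
    }
    tick("traces")
    write_traces_csv(traces, file.path(output_dir, "traces_dff.csv"))
  } else if (is.character(input)) {
    traces <- read_traces_csv(input)
    tick("traces")
  } else stop("unsupported input")

  features <- features_table(traces)
  tick("features")
  utils::write.csv(features, file.path(output_dir, "features.csv"),
                   row.names = FALSE)

  sync <- NULL
  sync_tab <- data.frame(roi = integer(0), mean_r = numeric(0),
                         excluded = logical(0))
  if (nrow(traces$dff) >= 2) {
    sync <- tryCatch(synchrony(traces, synchrony_threshold),
                     error = function(e) {
                       warning(conditionMessage(e)); NULL
                     })
  }
  if (!is.null(sync)) {
    sync_tab <- data.frame(roi = as.integer(names(sync$mean_r)),
                           mean_r = unname(sync$mean_r), excluded = FALSE)
    if (length(sync$excluded_rois)) {
      sync_tab <- rbind(sync_tab,
        data.frame(roi = as.integer(sync$excluded_rois),
                   mean_r = NA_real_, excluded = TRUE))
    }
    sync_tab <- sync_tab[order(sync_tab$roi), ]
  }
  tick("synchrony")
  utils::write.csv(sync_tab, file.path(output_dir, "synchrony.csv"),
                   row.names = FALSE)

  raster <- render_raster(traces, threshold = synchrony_threshold,
                          max_rois = max_raster_rois,
                          png_file = file.path(output_dir, "raster.png"),
                          csv_file = file.path(output_dir, "raster.csv"))
  tick("raster")

  report <- list(
    version = as.character(utils::packageVersion("calciwave")),
    n_frames = ncol(traces$dff),
    n_rois = if (!is.null(rois)) nrow(rois$table) else nrow(traces$dff),
    n_traces = nrow(traces$dff),
    n_excluded_fmin = length(traces$excluded),
    n_valid_features = sum(features$valid %in% TRUE),
    n_sync_rois = if (!is.null(sync)) length(sync$mean_r) else 0L,
    n_sync_excluded = if (!is.null(sync)) length(sync$excluded_rois) else 0L,
    synchrony_threshold = synchrony_threshold,
    seg_config = if (!is.null(rois)) unclass(seg) else NULL,
    stage_seconds = as.list(timings))
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(rois = rois, traces = traces, features = features,
                 synchrony = sync, report = report))
}

#' Raster display of the most active ROIs
#'
#' Orders ROIs by activity ([rank_activity()]), keeps the top
#' `max_rois`, and renders frames on the x axis against ROIs on the y axis
#' with intensity equal to dF (or a 0/1 supra-threshold indicator). The
#' plotted matrix is also written as CSV so the display is testable.
#'
#' @param traces a `cal_traces` (or bare dF matrix).
#' @param threshold dF cut used for ranking (and for binarized display).
#' @param max_rois rows displayed; default 100.
#' @param binarized plot supra-threshold indicators instead of dF.
#' @param png_file,csv_file optional output paths.
#' @return (invisibly) the raster matrix (ROIs x frames, most active first).
#' @export
render_raster <- function(traces, threshold = 0.15, max_rois = 100,
                          binarized = FALSE, png_file = NULL,
                          csv_file = NULL) {
  dff <- if (inherits(traces, "cal_traces")) traces$dff else traces
  labels <- if (inherits(traces, "cal_traces")) traces$roi_labels
            else seq_len(nrow(dff))
  if (nrow(dff) == 0) {
    m <- matrix(0, 0, ncol(dff))
  } else {
    ord <- rank_activity(traces, threshold)
    ord <- ord[seq_len(min(max_rois, length(ord)))]
    m <- dff[ord, , drop = FALSE]
    rownames(m) <- paste0("roi_", labels[ord])
    if (binarized) m <- (m > threshold) * 1
  }
  if (!is.null(csv_file)) utils::write.csv(m, csv_file, row.names = TRUE)
  if (!is.null(png_file)) {
    grDevices::png(png_file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    if (nrow(m) == 0) {
      graphics::plot.new()
      graphics::title(main = "raster: no ROIs")
    } else {
      graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                      z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                      col = grDevices::gray.colors(256, start = 1, end = 0),
                      xlab = "frame", ylab = "ROI (most active on top)",
                      useRaster = TRUE)
    }
  }
  invisible(m)
}

#' Direction-of-effect comparison between conditions
#'
#' Reports per-parameter medians per condition and the ordering of
#' conditions — a descriptive summary, explicitly not a hypothesis test.
#'
#' @param tables named list (one entry per condition) of lists with
#'   elements `features` (a [features_table()]) and optionally `mean_r`
#'   (numeric vector from [synchrony()]).
#' @param parameters feature columns to compare.
#' @return data frame: `parameter`, one `median_<condition>` column per
#'   condition, and `highest` (the condition with the largest median).
#' @export
compare_conditions <- function(tables,
                               parameters = c("amplitude", "pulse_width_s",
                                              "frequency_hz", "mean_r")) {
  if (length(tables) < 2) stop("need at least 2 conditions")
  conds <- names(tables)
  if (is.null(conds) || any(!nzchar(conds)))
    stop("'tables' must be a named list of conditions")
  med <- function(p, cond) {
    entry <- tables[[cond]]
    if (p == "mean_r") {
      if (is.null(entry$mean_r)) return(NA_real_)
      return(stats::median(entry$mean_r, na.rm = TRUE))
    }
    f <- entry$features
    v <- f[[p]][f$valid %in% TRUE]
    if (!length(v) || all(is.na(v))) NA_real_
    else stats::median(v, na.rm = TRUE)
  }
  out <- data.frame(parameter = parameters)
  for (cond in conds)
    out[[paste0("median_", cond)]] <- vapply(parameters, med,
                                             numeric(1), cond = cond)
  mcols <- paste0("median_", conds)
  out$highest <- apply(out[mcols], 1, function(r)
    if (all(is.na(r))) NA_character_ else conds[which.max(r)])
  out
}
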