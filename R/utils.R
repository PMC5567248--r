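# Internal helpers shared across modules.

# round half away from zero (ImageJ-style 8-bit conversion uses this,
# base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate expr with the RNG seeded from `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

#' Construct a fluorescence movie
#'
#' Wraps a `T x H x W` array of non-negative intensities together with its
#' frame rate. Frames are indexed `movie$data[t, , ]`; pixels follow the
#' `(row, col)` convention, 0-based in all reported coordinates.
#'
#' @param data numeric array, `T x H x W`, all values >= 0.
#' @param frame_rate acquisition rate in Hz (> 0).
#' @return an object of class `cal_movie` with elements `data` and
#'   `frame_rate`.
#' @export
cal_movie <- function(data, frame_rate) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a T x H x W array")
  if (dim(data)[1] < 1L) stop("movie must contain at least one frame")
  if (any(data < 0)) stop("movie intensities must be non-negative")
  stop_if_not_scalar_number(frame_rate, "frame_rate")
  if (frame_rate <= 0) stop("'frame_rate' must be > 0")
  structure(list(data = data, frame_rate = frame_rate), class = "cal_movie")
}

#' @export
print.cal_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cal_movie> %d frames of %d x %d px at %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[1] / x$frame_rate))
  invisible(x)
}

#' @export
print.cal_roiset <- function(x, ...) {
  cat(sprintf("<cal_roiset> %d ROI(s) on a %d x %d px grid (%d-connectivity)\n",
              nrow(x$table), nrow(x$label_image), ncol(x$label_image),
              x$connectivity))
  if (nrow(x$table)) {
    cat(sprintf("  area: %d-%d px^2 (median %g)\n",
                min(x$table$area), max(x$table$area),
                stats::median(x$table$area)))
  }
  invisible(x)
}

#' @export
print.cal_traces <- function(x, ...) {
  cat(sprintf("<cal_traces> %d ROI(s) x %d frames at %g Hz\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate))
  if (length(x$excluded))
    cat(sprintf("  excluded (F_min <= 0): %s\n",
                paste(x$excluded, collapse = ", ")))
  invisible(x)
}

#' @export
print.cal_synchrony <- function(x, ...) {
  cat(sprintf("<cal_synchrony> %d ROI(s), threshold dF > %g\n",
              length(x$mean_r) + length(x$excluded_rois), x$threshold))
  if (length(x$mean_r))
    cat(sprintf("  mean pairwise r: median %.3f (range %.3f to %.3f)\n",
                stats::median(x$mean_r), min(x$mean_r), max(x$mean_r)))
  if (length(x$excluded_rois))
    cat(sprintf("  excluded (zero variance after threshold): %s\n",
                paste(x$excluded_rois, collapse = ", ")))
  invisible(x)
}
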