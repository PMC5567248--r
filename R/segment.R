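# ROI segmentation reproducing the classic ImageJ macro chain:
# maximum-intensity projection -> 8-bit -> enhance contrast -> threshold ->
# remove outliers -> open (erode, dilate) -> watershed -> analyze particles.
# Images are numeric matrices [row, col]; masks are 0/1 matrices.

#' Segmentation configuration
#'
#' @param saturated_fraction total fraction of pixels saturated during
#'   contrast enhancement (half at each end); default 0.0035, the common
#'   0.35\% convention. Must satisfy `0 <= saturated_fraction < 0.1`.
#' @param threshold_method `"isodata"` (iterative intermeans, the ImageJ
#'   default family), `"otsu"`, or `"fixed"`.
#' @param fixed_threshold 0-255 threshold when `threshold_method = "fixed"`.
#' @param outlier_radius sliding-median radius in pixels (neighborhood is
#'   `(2r+1) x (2r+1)`).
#' @param outlier_delta brightness excess over the local median (8-bit
#'   units) above which a pixel is replaced.
#' @param morph_iterations opening iterations (erode then dilate, 3x3
#'   cross).
#' @param min_area,max_area particle-size limits in px^2.
#' @param connectivity 4 or 8 (default 8).
#' @return a `seg_config` list.
#' @export
seg_config <- function(saturated_fraction = 0.0035,
                       threshold_method = c("isodata", "otsu", "fixed"),
                       fixed_threshold = NULL, outlier_radius = 2,
                       outlier_delta = 50, morph_iterations = 1,
                       min_area = 30, max_area = 1500, connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  if (saturated_fraction < 0 || saturated_fraction >= 0.1)
    stop("'saturated_fraction' must lie in [0, 0.1)")
  if (min_area >= max_area) stop("'min_area' must be < 'max_area'")
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed threshold method requires 'fixed_threshold'")
  structure(list(saturated_fraction = saturated_fraction,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 outlier_radius = outlier_radius,
                 outlier_delta = outlier_delta,
                 morph_iterations = morph_iterations,
                 min_area = min_area, max_area = max_area,
                 connectivity = as.integer(connectivity)),
            class = "seg_config")
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum across all frames of the movie.
#'
#' @param movie a [cal_movie()] (or a bare `T x H x W` array).
#' @return `H x W` numeric matrix.
#' @export
max_intensity_projection <- function(movie) {
  data <- if (inherits(movie, "cal_movie")) movie$data else movie
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[1] < 1L)
    stop("movie must contain at least one frame")
  apply(data, c(2, 3), max)
}

#' Convert an image to 8-bit
#'
#' Linear map of `[min, max]` onto `[0, 255]` with round-half-away-from-zero
#' (the convention of integer image conversion). A constant image maps to
#' all zeros.
#'
#' @param image numeric matrix.
#' @return integer-valued matrix in `[0, 255]`.
#' @export
to_8bit <- function(image) {
  if (!length(image)) stop("empty image")
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(matrix(0, nrow(image), ncol(image)))
  round_half_away((image - lo) / (hi - lo) * 255)
}

#' Percentile contrast stretch
#'
#' Saturates `saturated_fraction` of the pixels (half at each end of the
#' histogram) and linearly rescales the remainder to `[0, 255]`: with
#' `k = floor(n * saturated_fraction / 2)` pixels clipped per tail, the ramp
#' runs from the `(k+1)`-th lowest to the `(k+1)`-th highest value.
#' `saturated_fraction = 0` is a plain min-max stretch. A constant image is
#' returned unchanged.
#'
#' @param image8 8-bit image matrix.
#' @param saturated_fraction fraction of pixels saturated in total.
#' @return 8-bit image matrix.
#' @export
enhance_contrast <- function(image8, saturated_fraction = 0.0035) {
  if (saturated_fraction < 0 || saturated_fraction >= 1)
    stop("'saturated_fraction' must lie in [0, 1)")
  v <- sort(as.numeric(image8))
  n <- length(v)
  k <- floor(n * saturated_fraction / 2)
  lo <- v[k + 1L]; hi <- v[n - k]
  if (hi <= lo) return(image8)
  out <- (image8 - lo) / (hi - lo) * 255
  out[] <- round_half_away(pmin(255, pmax(0, out)))
  out
}

# iterative intermeans (isodata) threshold on the 0..255 histogram;
# returns the integer threshold t: foreground is value > t
isodata_threshold <- function(image8) {
  counts <- tabulate(as.integer(image8) + 1L, nbins = 256L)
  vals <- 0:255
  t <- floor(sum(counts * vals) / sum(counts))  # start at the mean
  repeat {
    below <- counts[vals <= t]; above <- counts[vals > t]
    m1 <- if (sum(below)) sum(below * vals[vals <= t]) / sum(below) else t
    m2 <- if (sum(above)) sum(above * vals[vals > t]) / sum(above) else t
    t_new <- floor((m1 + m2) / 2)
    if (t_new == t) return(t)
    t <- t_new
  }
}

# Otsu's threshold by exhaustive between-class variance maximization
otsu_threshold <- function(image8) {
  counts <- tabulate(as.integer(image8) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  vals <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * vals)
  mu_t <- mu[256]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # the variance is flat across an empty histogram gap: take the plateau
  # midpoint rather than its edge
  best <- vals[sigma_b >= max(sigma_b) - 1e-9 * abs(max(sigma_b))]
  floor(mean(range(best)))
}

#' Threshold an 8-bit image to a binary mask
#'
#' Foreground is every pixel strictly above the threshold chosen by the
#' configured method (isodata by default).
#'
#' @param image8 8-bit image matrix.
#' @param config a [seg_config()] (or method/threshold given directly).
#' @return 0/1 mask matrix; attribute `"threshold"` records the cut used.
#' @export
binarize <- function(image8, config = seg_config()) {
  t <- switch(config$threshold_method,
    isodata = isodata_threshold(image8),
    otsu = otsu_threshold(image8),
    fixed = {
      if (is.null(config$fixed_threshold))
        stop("fixed threshold method requires 'fixed_threshold'")
      config$fixed_threshold
    })
  mask <- (image8 > t) * 1
  attr(mask, "threshold") <- t
  mask
}

# reflect-pad a matrix by r pixels on every side
reflect_pad <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(rev(seq_len(min(r, H))), seq_len(H), H + 1 - seq_len(min(r, H)))
  ci <- c(rev(seq_len(min(r, W))), seq_len(W), W + 1 - seq_len(min(r, W)))
  m[ri, ci, drop = FALSE]
}

#' Remove bright outlier pixels
#'
#' Replaces a pixel by the median of its `(2r+1) x (2r+1)` neighborhood
#' whenever the pixel exceeds that median by more than `delta`
#' (bright-outlier mode; the despeckle step of the segmentation chain).
#' Edges are handled by reflection. Works on 8-bit images and on 0/1 masks
#' alike.
#'
#' @param image numeric matrix (8-bit image or binary mask).
#' @param radius neighborhood radius, >= 1.
#' @param delta brightness excess over the local median triggering
#'   replacement.
#' @return matrix of the same type.
#' @export
remove_outliers <- function(image, radius = 2, delta = 50) {
  if (radius < 1) stop("'radius' must be >= 1")
  H <- nrow(image); W <- ncol(image)
  pad <- reflect_pad(image, radius)
  k <- 2 * radius + 1
  nb <- matrix(0, H * W, k * k)
  j <- 0L
  for (dc in 0:(k - 1)) for (dr in 0:(k - 1)) {
    j <- j + 1L
    nb[, j] <- as.numeric(pad[dr + seq_len(H), dc + seq_len(W)])
  }
  med <- apply(nb, 1, stats::median)
  out <- as.numeric(image)
  repl <- out - med > delta
  out[repl] <- med[repl]
  matrix(out, H, W)
}

# binary erosion/dilation with a 3x3 cross via shifted copies
shift_mat <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  rok <- rs >= 1 & rs <= H; cok <- cs >= 1 & cs <= W
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

erode_cross <- function(mask) {
  out <- mask
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    out <- out * shift_mat(mask, d[1], d[2], 0)
  out
}

dilate_cross <- function(mask) {
  out <- mask
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    out <- pmax(out, shift_mat(mask, d[1], d[2], 0))
  out
}

#' Morphological opening of a binary mask
#'
#' `morph_iterations` erosions followed by the same number of dilations
#' with a 3x3 cross: removes hairline bridges and specks while approximately
#' preserving the area of large blobs.
#'
#' @param mask 0/1 matrix.
#' @param morph_iterations iterations of each half of the opening.
#' @return 0/1 matrix.
#' @export
refine_mask <- function(mask, morph_iterations = 1) {
  out <- mask
  for (i in seq_len(morph_iterations)) out <- erode_cross(out)
  for (i in seq_len(morph_iterations)) out <- dilate_cross(out)
  out
}

#' Watershed splitting of touching blobs
#'
#' Distance-transform watershed on the foreground: each basin of the
#' distance map becomes one object, and pixels where distinct basins meet
#' are reassigned to background, cutting touching convex blobs apart with a
#' thin background ridge at the saddle. Isolated blobs pass through with at
#' most rim pixels altered (in practice unchanged).
#'
#' @param mask 0/1 matrix.
#' @param tolerance minimum height of a distance-map maximum relative to its
#'   surroundings for it to seed its own basin (passed to the flooding);
#'   default 1 px suppresses splits caused by pixel-level rim roughness.
#' @return 0/1 matrix with separating ridges removed from the foreground.
#' @export
watershed_split <- function(mask, tolerance = 1) {
  if (!sum(mask)) return(mask)
  dist <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dist, tolerance = tolerance, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(mask), ncol(mask))
  # ridge: foreground pixel adjacent (8-neighborhood) to a different label
  ridge <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shift_mat(labels, dr, dc, 0L)
    ridge <- ridge | (labels > 0 & nb > 0 & nb != labels)
  }
  out <- mask
  out[ridge] <- 0
  out
}

# connected-component labeling in raster-scan order of each component's
# first pixel (row-major), 4- or 8-connectivity; returns integer label matrix
label_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask > 0)
  if (!length(fg)) return(lab)
  # raster order: by row, then column (R indices are column-major)
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  fg <- fg[order(rows, cols)]
  offs <- if (connectivity == 8)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  next_label <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    next_label <- next_label + 1L
    frontier <- seed
    lab[seed] <- next_label
    while (length(frontier)) {
      r <- ((frontier - 1L) %% H) + 1L
      c <- ((frontier - 1L) %/% H) + 1L
      nxt <- integer(0)
      for (d in offs) {
        rr <- r + d[1]; cc <- c + d[2]
        ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        idx <- rr[ok] + (cc[ok] - 1L) * H
        idx <- idx[mask[idx] > 0 & lab[idx] == 0L]
        if (length(idx)) {
          idx <- unique(idx)
          lab[idx] <- next_label
          nxt <- c(nxt, idx)
        }
      }
      frontier <- nxt
    }
  }
  lab
}

#' Size-limited particle analysis
#'
#' Labels connected components of a binary mask (in raster-scan order of
#' each component's first pixel), discards components outside
#' `[min_area, max_area]`, and renumbers the survivors consecutively.
#'
#' @param mask 0/1 matrix.
#' @param min_area,max_area inclusive area limits in px^2.
#' @param connectivity 4 or 8.
#' @return a `cal_roiset`: `label_image` (`H x W` integer matrix, 0 =
#'   background) plus a `table` data frame with `label`, `area`,
#'   `centroid_row`/`centroid_col` (0-based), and half-open bounding box
#'   `bbox_row0/row1/col0/col1`.
#' @export
analyze_particles <- function(mask, min_area = 30, max_area = 1500,
                              connectivity = 8) {
  if (min_area >= max_area) stop("'min_area' must be < 'max_area'")
  lab <- label_components(mask, connectivity)
  K <- max(lab)
  keep <- integer(0)
  if (K > 0) {
    areas <- tabulate(lab[lab > 0], nbins = K)
    keep <- which(areas >= min_area & areas <= max_area)
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  rows <- list()
  for (i in seq_along(keep)) {
    px <- which(lab == keep[i])
    out[px] <- i
    r <- ((px - 1L) %% nrow(mask))        # 0-based
    c <- ((px - 1L) %/% nrow(mask))
    rows[[i]] <- data.frame(label = i, area = length(px),
                            centroid_row = mean(r), centroid_col = mean(c),
                            bbox_row0 = min(r), bbox_row1 = max(r) + 1L,
                            bbox_col0 = min(c), bbox_col1 = max(c) + 1L)
  }
  table <- if (length(rows)) do.call(rbind, rows)
    else data.frame(label = integer(0), area = integer(0),
                    centroid_row = numeric(0), centroid_col = numeric(0),
                    bbox_row0 = integer(0), bbox_row1 = integer(0),
                    bbox_col0 = integer(0), bbox_col1 = integer(0))
  structure(list(label_image = out, table = table,
                 connectivity = as.integer(connectivity)),
            class = "cal_roiset")
}

#' Segment a movie into ROIs
#'
#' The full automated chain: maximum-intensity projection, 8-bit
#' conversion, percentile contrast stretch, thresholding, bright-outlier
#' removal, morphological opening, distance-transform watershed, and
#' size-limited particle analysis. Deterministic for fixed input and
#' config.
#'
#' @param movie a [cal_movie()].
#' @param config a [seg_config()].
#' @param keep_intermediates if `TRUE`, every intermediate image is attached
#'   as the `"intermediates"` attribute for auditing.
#' @return a `cal_roiset` (see [analyze_particles()]).
#' @export
segment <- function(movie, config = seg_config(), keep_intermediates = FALSE) {
  mip <- max_intensity_projection(movie)
  img8 <- to_8bit(mip)
  enh <- enhance_contrast(img8, config$saturated_fraction)
  mask <- binarize(enh, config)
  thr <- attr(mask, "threshold")
  clean <- remove_outliers(mask, config$outlier_radius,
                           delta = 0.5)  # on a 0/1 mask any excess is salt
  opened <- refine_mask(clean, config$morph_iterations)
  split <- watershed_split(opened)
  rois <- analyze_particles(split, config$min_area, config$max_area,
                            config$connectivity)
  if (keep_intermediates)
    attr(rois, "intermediates") <- list(mip = mip, img8 = img8,
                                        enhanced = enh, mask = mask,
                                        threshold = thr, cleaned = clean,
                                        opened = opened, split = split)
  rois
}

#' Count ground-truth centers per ROI
#'
#' For auditing ROI-to-cell correspondence: each 0-based `(row, col)` center
#' is assigned to the ROI label at its (rounded) pixel, and the histogram of
#' centers per ROI is reported as the fraction of ROIs containing 1, 2, or
#' >= 3 centers (ROIs with 0 centers are reported separately).
#'
#' @param rois a `cal_roiset`.
#' @param centers numeric matrix, centers x 2, 0-based `(row, col)`.
#' @return list with `per_roi` (integer center count per ROI label) and the
#'   fractions of all ROIs containing exactly 1, exactly 2, or >= 3 centers
#'   (`fraction_1`, `fraction_2`, `fraction_3plus`), plus `fraction_le2`.
#' @export
count_centers_per_roi <- function(rois, centers) {
  lab <- rois$label_image
  K <- nrow(rois$table)
  per_roi <- integer(K)
  if (length(centers)) {
    r <- round(centers[, 1]) + 1L
    c <- round(centers[, 2]) + 1L
    ok <- r >= 1 & r <= nrow(lab) & c >= 1 & c <= ncol(lab)
    hits <- lab[cbind(r[ok], c[ok])]
    hits <- hits[hits > 0]
    if (length(hits)) {
      tab <- tabulate(hits, nbins = K)
      per_roi <- tab
    }
  }
  if (K == 0)
    return(list(per_roi = per_roi, fraction_1 = NaN, fraction_2 = NaN,
                fraction_3plus = NaN, fraction_le2 = NaN))
  list(per_roi = per_roi,
       fraction_1 = mean(per_roi == 1),
       fraction_2 = mean(per_roi == 2),
       fraction_3plus = mean(per_roi >= 3),
       fraction_le2 = mean(per_roi <= 2))
}
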