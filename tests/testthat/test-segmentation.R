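# Segmentation chain: each stage against a brute-force oracle, then the
# composed macro on simulated fields.

test_that("maximum-intensity projection is the per-pixel max", {
  frames <- array(0, dim = c(2, 2, 2))
  frames[1, , ] <- rbind(c(1, 2), c(3, 0))
  frames[2, , ] <- rbind(c(0, 5), c(1, 1))
  expect_equal(max_intensity_projection(frames), rbind(c(1, 5), c(3, 1)))

  single <- array(rbind(c(4, 7), c(2, 9)), dim = c(1, 2, 2))
  expect_equal(max_intensity_projection(single), rbind(c(4, 7), c(2, 9)))

  set.seed(21)
  mv <- array(runif(10 * 8 * 8, 0, 100), dim = c(10, 8, 8))
  brute <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8) brute[r, c] <- max(mv[, r, c])
  expect_equal(max_intensity_projection(mv), brute)
})

test_that("8-bit conversion maps [min, max] linearly with half-away rounding", {
  img <- rbind(c(0, 255), c(510, 100))
  out <- to_8bit(img)
  expect_equal(out[1, 2], 128)       # round(255 * 255/510) half away -> 128
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 255)
  expect_equal(to_8bit(matrix(7, 3, 3)), matrix(0, 3, 3))
  keep <- rbind(c(0, 255), c(255, 0))
  expect_equal(to_8bit(keep), keep)
  # offset and gain invariance of the mapping
  set.seed(4); r <- matrix(runif(64, 0, 1000), 8, 8)
  expect_equal(to_8bit(r), to_8bit(3 * r + 123))
})

test_that("contrast stretch saturates the configured pixel fraction", {
  img <- matrix(0:99, 10, 10)
  out <- enhance_contrast(img, 0.02)   # 1 px clipped per tail: ramp 1..98
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  # quantile oracle on the sorted array
  lo <- 1; hi <- 98
  expected <- img
  expected[] <- pmin(255, pmax(0, (img - lo) / (hi - lo) * 255))
  expected[] <- sign(expected) * floor(abs(expected) + 0.5)
  expect_equal(out, expected)
  # zero saturation is a plain min-max stretch
  minmax <- img
  minmax[] <- sign(img / 99 * 255) * floor(abs(img / 99 * 255) + 0.5)
  expect_equal(enhance_contrast(img, 0), minmax)
  # degenerate image unchanged
  expect_equal(enhance_contrast(matrix(9, 4, 4), 0.02), matrix(9, 4, 4))
})

test_that("isodata threshold separates a bimodal image", {
  set.seed(8)
  img <- matrix(10, 40, 40)
  img[10:20, 10:20] <- 200
  mask <- binarize(img, seg_config(threshold_method = "isodata"))
  thr <- attr(mask, "threshold")
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_equal(thr, oracle_isodata(as.numeric(img)))
  expect_true(all(mask[10:20, 10:20] == 1))
  expect_true(all(mask[30:40, 30:40] == 0))
  # fixed threshold is a plain cut
  fx <- binarize(matrix(c(100, 200), 1, 2),
                 seg_config(threshold_method = "fixed", fixed_threshold = 128))
  expect_equal(as.numeric(fx), c(0, 1))
  expect_error(binarize(img, seg_config(threshold_method = "fixed")),
               "fixed_threshold")
  # flat background image gives an empty mask
  expect_equal(sum(binarize(matrix(5, 10, 10), seg_config())), 0)
})

test_that("otsu threshold lies between well-separated modes", {
  set.seed(9)
  img <- matrix(round(c(rnorm(500, 30, 5), rnorm(500, 200, 5))), 25, 40)
  img <- pmin(255, pmax(0, img))
  mask <- binarize(img, seg_config(threshold_method = "otsu"))
  expect_gt(attr(mask, "threshold"), 50)
  expect_lt(attr(mask, "threshold"), 180)
})

test_that("outlier removal matches the sliding-median oracle", {
  # isolated salt pixel disappears
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  expect_equal(sum(remove_outliers(m, radius = 2, delta = 0.5)), 0)
  # solid block: interior pixels see a median equal to their own value;
  # only extreme corner pixels (local minority) can be trimmed
  blk <- matrix(0, 14, 14); blk[3:12, 3:12] <- 1
  out_blk <- remove_outliers(blk, 2, 0.5)
  expect_equal(out_blk[5:10, 5:10], blk[5:10, 5:10])
  expect_equal(out_blk, oracle_remove_outliers(blk, 2, 0.5))
  # random salt on a disk: equals the brute-force sliding median
  set.seed(31)
  img <- disk_mask(20, 20, matrix(c(10, 10), 1), 5) * 180
  salt <- sample(400, 15)
  img[salt] <- pmax(img[salt], 250)
  out <- remove_outliers(img, 2, 50)
  expect_equal(out, oracle_remove_outliers(img, 2, 50))
  expect_error(remove_outliers(img, radius = 0), "radius")
})

test_that("morphological opening matches the oracle and kills thin lines", {
  line <- matrix(0, 10, 10); line[5, 2:9] <- 1
  expect_equal(sum(refine_mask(line, 1)), 0)
  sq <- matrix(0, 13, 13); sq[3:11, 3:11] <- 1
  expect_equal(refine_mask(sq, 1), oracle_open_cross(sq, 1))
  expect_equal(refine_mask(matrix(0, 6, 6), 1), matrix(0, 6, 6))
  # large-blob area is approximately preserved (within 15%)
  blob <- disk_mask(30, 30, matrix(c(15, 15), 1), 9)
  expect_lt(abs(sum(refine_mask(blob, 1)) - sum(blob)) / sum(blob), 0.15)
  # random masks equal the oracle for 1 and 2 iterations
  set.seed(14)
  for (it in 1:2) {
    rm_ <- matrix(rbinom(12 * 12, 1, 0.5), 12, 12)
    expect_equal(refine_mask(rm_, it), oracle_open_cross(rm_, it))
  }
})

test_that("watershed separates touching disks and spares isolated ones", {
  two <- disk_mask(40, 60, rbind(c(20, 22), c(20, 34)), c(8, 8))
  expect_equal(oracle_component_count(two, 8), 1)   # they overlap
  split <- watershed_split(two)
  expect_equal(oracle_component_count(split, 8), 2)
  one <- disk_mask(30, 30, matrix(c(15, 15), 1), 8)
  expect_equal(watershed_split(one), one)
  empty <- matrix(0, 10, 10)
  expect_equal(watershed_split(empty), empty)
})

test_that("particle analysis filters by area and labels consecutively", {
  m <- matrix(0, 30, 30)
  m[2:9, 2:6] <- 1                      # 40 px
  rois <- analyze_particles(m, 30, 500, 8)
  expect_equal(nrow(rois$table), 1)
  expect_equal(rois$table$area, 40)
  small <- matrix(0, 20, 20); small[2:6, 3:4] <- 1   # 10 px
  expect_equal(nrow(analyze_particles(small, 30, 500, 8)$table), 0)
  expect_error(analyze_particles(m, 500, 30), "min_area")

  # random blobs: component count after filtering equals flood-fill oracle
  set.seed(77)
  rnd <- matrix(rbinom(40 * 40, 1, 0.35), 40, 40)
  for (conn in c(4, 8)) {
    lab <- analyze_particles(rnd, 1, 10000, conn)
    expect_equal(nrow(lab$table), oracle_component_count(rnd, conn))
    # labels are exactly 0..K with every 1..K present
    expect_setequal(unique(as.integer(lab$label_image)),
                    0:nrow(lab$table))
    # connectivity invariant: each ROI is one connected component
    for (k in seq_len(nrow(lab$table))) {
      expect_equal(oracle_component_count((lab$label_image == k) * 1, conn), 1)
    }
  }
})

test_that("particle labels follow raster-scan order of first pixels", {
  m <- matrix(0, 20, 20)
  m[12:15, 2:5] <- 1     # first pixel later in raster order (row 12)
  m[2:5, 12:15] <- 1     # first pixel earlier (row 2)
  rois <- analyze_particles(m, 1, 100, 8)
  expect_equal(nrow(rois$table), 2)
  # label 1 must be the blob whose first raster pixel comes first (row 2)
  expect_lt(rois$table$bbox_row0[1], rois$table$bbox_row0[2])
})

test_that("segment recovers well-separated simulated cells", {
  cfg <- sim_config(n_cells = 25, field_size = c(150, 150), n_frames = 150,
                    event_rate = 0.2, sync_mode = "asynchronous",
                    noise = noise_model(shot_noise = FALSE, gaussian_sd = 0,
                                        background_gradient = 0.05),
                    seed = 19)
  sim <- simulate_movie(cfg)
  rois <- segment(sim$movie)
  cc <- count_centers_per_roi(rois, sim$truth$cell_centers)
  # every ROI holds exactly one truth center, and nearly all cells found
  expect_equal(cc$fraction_1, 1)
  expect_gte(sum(cc$per_roi > 0), 24)
  # every emitted ROI respects the configured area limits
  expect_true(all(rois$table$area >= 30 & rois$table$area <= 1500))
  # blank movie: zero ROIs
  blank <- cal_movie(array(100, dim = c(5, 40, 40)), 5)
  expect_equal(nrow(segment(blank)$table), 0)
})

test_that("segmentation is deterministic and offset/gain invariant", {
  cfg <- sim_config(n_cells = 10, field_size = c(96, 96), n_frames = 80,
                    event_rate = 0.2, seed = 23)
  sim <- simulate_movie(cfg)
  a <- segment(sim$movie)
  b <- segment(sim$movie)
  expect_identical(a$label_image, b$label_image)
  shifted <- cal_movie(sim$movie$data + 500, sim$movie$frame_rate)
  expect_identical(segment(shifted)$label_image, a$label_image)
  scaled <- cal_movie(sim$movie$data * 3, sim$movie$frame_rate)
  expect_identical(segment(scaled)$label_image, a$label_image)
})

test_that("center counting matches a brute-force point-in-label test", {
  m <- matrix(0, 30, 30)
  m[3:10, 3:10] <- 1; m[15:22, 15:22] <- 1
  rois <- analyze_particles(m, 10, 500, 8)
  centers <- rbind(c(5, 5), c(17, 17), c(20, 20), c(28, 2))  # 0-based
  cc <- count_centers_per_roi(rois, centers)
  brute <- integer(nrow(rois$table))
  for (i in seq_len(nrow(centers))) {
    lab <- rois$label_image[centers[i, 1] + 1, centers[i, 2] + 1]
    if (lab > 0) brute[lab] <- brute[lab] + 1L
  }
  expect_equal(cc$per_roi, brute)
  expect_equal(cc$fraction_1, 0.5)
  expect_equal(cc$fraction_2, 0.5)
  expect_equal(cc$fraction_le2, 1)
})
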