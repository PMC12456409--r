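test_that("spec validation keeps the nucleus inside the cell", {
  expect_error(polarized_cell_spec(nucleus_offset = -18),
               class = "dcmotion_parameter_error")
  expect_error(polarized_cell_spec(nucleus_radius = 8),
               class = "dcmotion_parameter_error")
  expect_error(polarized_cell_spec(rear_front_ratio = 0),
               class = "dcmotion_parameter_error")
  expect_silent(polarized_cell_spec())
})

test_that("uniform noiseless cell measures ratio 1 on the truth mask", {
  img <- generate_polarized_cell_image(
    polarized_cell_spec(rear_front_ratio = 1, noise_sd = 0))
  geom <- compute_geometry(img$channels$mask_truth > 0,
                           img$channels$nucleus > 0.5, img$pixel_size)
  expect_identical(rear_front_ratio(img, geom), 1)
})

test_that("an offset nucleus puts the rear on its side of the cell", {
  img <- generate_polarized_cell_image(polarized_cell_spec(
    nucleus_offset = -8, noise_sd = 0))
  geom <- compute_geometry(img$channels$mask_truth > 0,
                           img$channels$nucleus > 0.5, img$pixel_size)
  expect_lt(geom$rear_distance, geom$front_distance)
  # 40 um cell, nucleus centre at -8 um with radius 4: edges at 8 and 24 um
  expect_equal(geom$rear_distance, 8, tolerance = 0.3)
  expect_equal(geom$front_distance, 24, tolerance = 0.3)
  # the axis points to the front (+x here)
  expect_gt(geom$axis[1], 0.99)
})

test_that("segmentation recovers the truth ellipse within a 1-px band", {
  img <- generate_polarized_cell_image(polarized_cell_spec(seed = 2))
  mask <- segment_cell(img, "signal")
  truth <- img$channels$mask_truth > 0
  # disagreement only at the boundary: erode/dilate the truth by 1 px
  kern <- EBImage::makeBrush(3, "box")
  shrunk <- EBImage::imageData(EBImage::erode(EBImage::Image(truth * 1),
                                              kern)) > 0
  grown <- EBImage::imageData(EBImage::dilate(EBImage::Image(truth * 1),
                                              kern)) > 0
  expect_true(all(mask[shrunk]))
  expect_true(all(!mask[!grown]))
})

test_that("segmentation rejects empty images and keeps the larger object", {
  img0 <- cell_image(list(signal = matrix(0, 20, 20)), 0.2)
  expect_error(segment_cell(img0, "signal"),
               class = "dcmotion_segmentation_error")
  two <- matrix(0, 30, 40)
  two[5:10, 5:10] <- 100    # 36 px
  two[15:25, 20:32] <- 100  # 143 px
  imgt <- cell_image(list(signal = two), 0.2)
  m <- segment_cell(imgt, "signal")
  expect_true(all(m[15:25, 20:32]))
  expect_false(any(m[5:10, 5:10]))
})

test_that("pipeline recovers a rear:front ratio of 2 within 5% over 20 seeds", {
  ratios <- vapply(1:20, function(i) {
    sc <- segmented_cell(polarized_cell_spec(
      rear_front_ratio = 2, noise_sd = 5, seed = i))
    expect_lte(sc$geom$rear_distance, sc$geom$front_distance)
    rear_front_ratio(sc$img, sc$geom)
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.05)
  expect_true(all(abs(ratios - 2) / 2 < 0.05))
})

test_that("generator ground-truth distances are recovered within 1 px", {
  px <- 0.2
  for (i in 1:5) {
    off <- c(-10, -8, -6, 6, 9)[i]
    sc <- segmented_cell(polarized_cell_spec(nucleus_offset = off,
                                             noise_sd = 5, seed = i))
    true_rear <- 20 - abs(off) - 4
    true_front <- 20 + abs(off) - 4
    expect_equal(sc$geom$rear_distance, true_rear, tolerance = 2 * px)
    expect_equal(sc$geom$front_distance, true_front, tolerance = 2 * px)
  }
})

test_that("mirroring the cell inverts the rear/front ratio", {
  img <- generate_polarized_cell_image(polarized_cell_spec(
    rear_front_ratio = 2, noise_sd = 0, seed = 3))
  geom <- compute_geometry(img$channels$mask_truth > 0,
                           img$channels$nucleus > 0.5, img$pixel_size)
  r <- rear_front_ratio(img, geom)
  mirror <- function(m) m[, rev(seq_len(ncol(m)))]
  img_m <- cell_image(lapply(img$channels, mirror), img$pixel_size)
  geom_m <- compute_geometry(img_m$channels$mask_truth > 0,
                             img_m$channels$nucleus > 0.5, img_m$pixel_size)
  r_m <- rear_front_ratio(img_m, geom_m)
  # the rear stays with the nucleus, so the measured ratio is unchanged
  expect_equal(r_m, r, tolerance = 1e-6)

  # with a centred nucleus the partition line maps onto itself under
  # mirroring, so the ratios of image and mirrored image are reciprocals
  img_c <- generate_polarized_cell_image(polarized_cell_spec(
    nucleus_offset = 0, rear_front_ratio = 2, noise_sd = 0, seed = 4))
  gm <- function(im) suppressMessages(compute_geometry(
    im$channels$mask_truth > 0, im$channels$nucleus > 0.5, im$pixel_size))
  img_cm <- cell_image(lapply(img_c$channels, mirror), img_c$pixel_size)
  prod <- rear_front_ratio(img_c, gm(img_c)) *
    rear_front_ratio(img_cm, gm(img_cm))
  expect_equal(prod, 1, tolerance = 1e-9)
})

test_that("symmetric cells tie and resolve rear deterministically", {
  img <- generate_polarized_cell_image(polarized_cell_spec(
    nucleus_offset = 0, rear_front_ratio = 1, noise_sd = 0))
  expect_message(
    geom <- compute_geometry(img$channels$mask_truth > 0,
                             img$channels$nucleus > 0.5, img$pixel_size),
    "tie")
  expect_true(geom$tie)
  expect_equal(geom$rear_distance, geom$front_distance,
               tolerance = img$pixel_size)
})

test_that("enlarging the canvas changes no measurement", {
  sc <- segmented_cell(polarized_cell_spec(seed = 6))
  r0 <- rear_front_ratio(sc$img, sc$geom)
  pad <- function(m, extra = 30) {
    out <- matrix(0, nrow(m) + extra, ncol(m) + extra)
    out[seq_len(nrow(m)) + 15, seq_len(ncol(m)) + 15] <- m
    out
  }
  big <- cell_image(lapply(sc$img$channels, pad), sc$img$pixel_size)
  cmask <- segment_cell(big, "signal")
  geom <- compute_geometry(cmask, big$channels$nucleus > 0.5, big$pixel_size)
  expect_equal(rear_front_ratio(big, geom), r0, tolerance = 1e-9)
  expect_equal(geom$rear_distance, sc$geom$rear_distance, tolerance = 1e-9)
})

test_that("width-averaged profiles are normalized per cell and reflect polarity", {
  img <- generate_polarized_cell_image(polarized_cell_spec(
    rear_front_ratio = 1, noise_sd = 0))
  geom <- compute_geometry(img$channels$mask_truth > 0,
                           img$channels$nucleus > 0.5, img$pixel_size)
  flat <- width_averaged_profile(img, geom)
  expect_equal(max(flat$intensity), 1)
  expect_true(all(abs(flat$intensity - 1) < 1e-9))
  expect_equal(nrow(flat), round(25 / img$pixel_size))

  # rear-bright cell: profile from the rear starts at ~1, steps down past
  # the nucleus midline (rear extends 12 um from the rear edge here)
  img2 <- generate_polarized_cell_image(polarized_cell_spec(
    rear_front_ratio = 2, noise_sd = 0))
  geom2 <- compute_geometry(img2$channels$mask_truth > 0,
                            img2$channels$nucleus > 0.5, img2$pixel_size)
  prof <- width_averaged_profile(img2, geom2, from_end = "rear")
  expect_equal(max(prof$intensity), 1)
  expect_true(all(prof$intensity[prof$offset_um < 11] > 0.95))
  expect_true(all(prof$intensity[prof$offset_um > 13] < 0.55))

  # group averaging: per-offset mean of per-cell normalized profiles
  agg <- aggregate_profiles(list(flat, prof))
  k <- which(agg$offset_um > 13 & agg$offset_um < 20)
  expect_equal(agg$mean_intensity[k],
               (flat$intensity[k] + prof$intensity[k]) / 2)
  expect_true(all(agg$n_cells == 2))
})

test_that("profiles truncate with a warning when the cell is short", {
  sc <- segmented_cell(polarized_cell_spec(cell_axes = c(16, 10),
                                           nucleus_offset = -3,
                                           nucleus_radius = 3, seed = 1))
  expect_warning(p <- width_averaged_profile(sc$img, sc$geom, length = 25),
                 "truncated")
  expect_lt(nrow(p), round(25 / sc$img$pixel_size))
})

test_that("foci are counted per unit area and recovered exactly", {
  px <- 0.5
  im <- matrix(0, 40, 50)
  mask <- matrix(TRUE, 40, 50)
  centers <- cbind(r = c(5, 5, 20, 20, 35, 35, 20),
                   c = c(10, 40, 10, 40, 10, 40, 25))
  for (k in seq_len(nrow(centers)))
    im[centers[k, 1] + (-1:1), centers[k, 2] + (-1:1)] <- 50
  img <- cell_image(list(signal = im), px)
  res <- count_foci(img, mask, threshold = 10)
  expect_equal(res$count, 7L)
  expect_equal(res$area_um2, 40 * 50 * px^2)
  expect_equal(res$density, 7 / (40 * 50 * px^2))
  # empty channel counts zero
  img0 <- cell_image(list(signal = matrix(0, 40, 50)), px)
  expect_equal(count_foci(img0, mask, threshold = 10)$count, 0L)
  # min_area filters the single-pixel focus out
  im2 <- im; im2[2, 2] <- 50
  img2 <- cell_image(list(signal = im2), px)
  expect_equal(count_foci(img2, mask, threshold = 10,
                          min_area = 2 * px^2)$count, 7L)
})

test_that("planted focus counts are recovered over seeds", {
  px <- 0.5
  for (i in 1:20) {
    n_true <- 3 + (i %% 5)
    im <- matrix(0, 60, 60)
    pool <- as.matrix(expand.grid(seq(5, 55, by = 10), seq(5, 55, by = 10)))
    pos <- dcmotion:::with_seed(i, pool[sample(nrow(pool), n_true), ,
                                        drop = FALSE])
    for (k in seq_len(n_true))
      im[pos[k, 1] + (-1:1), pos[k, 2] + (-1:1)] <- 80
    img <- cell_image(list(signal = im), px)
    expect_equal(count_foci(img, matrix(TRUE, 60, 60),
                            threshold = 10)$count, n_true)
  }
})

test_that("region counting is rotation-invariant for an annulus", {
  px <- 1
  dims <- c(101, 101)
  center <- c(50.5, 50.5)
  im <- matrix(0, dims[1], dims[2])
  # 12 objects on a ring of radius 30 um
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  for (a in ang) {
    r <- round(50.5 + 30 * sin(a)); c <- round(50.5 + 30 * cos(a))
    im[r + (-1:1), c + (-1:1)] <- 90
  }
  img <- cell_image(list(signal = im), px)
  ann <- annulus_mask(dims, center, 25, 35, px)
  expect_equal(count_objects_in_region(img, ann, threshold = 10), 12L)
  # rotating the scene by 90 degrees leaves the count unchanged
  rot90 <- function(m) t(m[nrow(m):1, ])
  img_r <- cell_image(list(signal = rot90(im)), px)
  expect_equal(count_objects_in_region(img_r, ann, threshold = 10), 12L)
  # empty region counts zero
  expect_equal(count_objects_in_region(img, annulus_mask(dims, center,
                                                         45, 49, px),
                                       threshold = 10), 0L)
})
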