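# Core image operations: level conversion, ratio map, ROI masking,
# top-fraction extraction, rendering, contour overlay.

test_that("rescale_intensity implements the affine level conversion", {
  m <- matrix(c(0, 2048, 4095), 1, 3)
  out <- rescale_intensity(m)
  expect_identical(out[1, ], c(0L, 128L, 255L))
  expect_equal(out[1, 2], floor(2048 / 4095 * 255 + 0.5))  # independent arithmetic

  # monotone, bounded, and clipping reported
  x <- matrix(sort(runif(100, -50, 4200)), 10, 10)
  expect_warning(out <- rescale_intensity(x), "clipped")
  expect_true(all(out >= 0L & out <= 255L))
  expect_true(all(diff(as.vector(out)[order(as.vector(x))]) >= 0L))

  expect_error(conversion_spec(x_min = 5, x_max = 5), "degenerate")
})

test_that("water_oil_ratio divides elementwise under the zero-fat policy", {
  w <- raw_image_matrix(matrix(c(50L, 10L, 7L, 0L), 2, 2), "water")
  f <- raw_image_matrix(matrix(c(25L, 10L, 0L, 0L), 2, 2), "fat")
  r <- water_oil_ratio(w, f, ratio_policy(zero_fat_cap = 1000))
  expect_equal(r[1, 1], 2.0)
  expect_equal(r[2, 1], 1.0)
  expect_equal(r[1, 2], 1000)   # fat 0, water 7 -> capped
  expect_equal(r[2, 2], 0)      # 0/0 -> 0
  expect_identical(attr(r, "n_capped"), 1L)
  expect_identical(provenance(r), "full")

  same <- raw_image_matrix(matrix(3L, 4, 4), "water")
  samef <- raw_image_matrix(matrix(3L, 4, 4), "fat")
  expect_true(all(water_oil_ratio(same, samef) == 1))

  expect_error(water_oil_ratio(w, raw_image_matrix(matrix(1L, 3, 2), "fat")),
               "shape mismatch")
  expect_error(water_oil_ratio(f, w), "channel mismatch")
})

test_that("ratio of swapped positive inputs is the elementwise reciprocal", {
  set.seed(11)
  a <- matrix(sample(1:4095, 64), 8, 8)
  b <- matrix(sample(1:4095, 64), 8, 8)
  r1 <- water_oil_ratio(raw_image_matrix(a, "water"), raw_image_matrix(b, "fat"))
  r2 <- water_oil_ratio(raw_image_matrix(b, "water"), raw_image_matrix(a, "fat"))
  expect_equal(as.vector(r1) * as.vector(r2), rep(1, 64))
})

test_that("apply_roi zeroes exactly the out-of-ROI voxels and is idempotent-by-provenance", {
  set.seed(21)
  vals <- matrix(runif(64, 0, 10), 8, 8)
  r <- ratio_matrix(vals, "full")

  all_true <- roi_mask(matrix(TRUE, 8, 8))
  expect_equal(unclass(apply_roi(r, all_true))[, ], vals, ignore_attr = TRUE)

  all_false <- roi_mask(matrix(FALSE, 8, 8))
  expect_true(all(apply_roi(r, all_false) == 0))

  checker <- suppressWarnings(roi_mask(matrix(rep(c(TRUE, FALSE), 32), 8, 8)))
  got <- apply_roi(r, checker)
  expect_equal(matrix(as.numeric(got), 8, 8),
               oracle_apply_roi(vals, checker$in_roi))
  expect_identical(provenance(got), "roi_masked")

  # masking twice equals once (reapply on a fresh full copy)
  again <- apply_roi(ratio_matrix(matrix(as.numeric(got), 8, 8), "full"), checker)
  expect_equal(as.numeric(again), as.numeric(got))

  expect_error(apply_roi(got, checker), "full")
  expect_error(apply_roi(r, roi_mask(matrix(TRUE, 4, 4))), "shape mismatch")
})

test_that("extract_brown_fat keeps exactly the top fraction with deterministic ties", {
  # 1000 distinct values, 1% -> the 10 largest
  set.seed(31)
  h <- 25; w <- 40
  vals <- matrix(sample(seq_len(1000)) / 7, h, w)
  mask <- roi_mask(matrix(TRUE, h, w))
  pr <- apply_roi(ratio_matrix(vals, "full"), mask)
  ex <- extract_brown_fat(pr, mask, extraction_spec(0.01))
  expect_identical(ex$k, 10L)
  expect_setequal(ex$bprwo[ex$bprwo > 0], sort(vals, decreasing = TRUE)[1:10])
  expect_identical(provenance(ex$bprwo), "brown_extracted")

  # full retention reproduces the input
  ex_all <- extract_brown_fat(pr, mask, extraction_spec(1.0))
  expect_equal(as.numeric(ex_all$bprwo), as.numeric(pr))
  expect_identical(nrow(ex_all$retained_indices), as.integer(h * w))

  # all-equal values, N = 200, 1% -> the 2 smallest row-major indices
  m2 <- roi_mask(matrix(TRUE, 10, 20))
  pr2 <- apply_roi(ratio_matrix(matrix(3.5, 10, 20), "full"), m2)
  ex2 <- extract_brown_fat(pr2, m2, extraction_spec(0.01))
  expect_identical(ex2$k, 2L)
  expect_equal(unname(ex2$retained_indices),
               unname(oracle_extract_indices(matrix(3.5, 10, 20), m2$in_roi, 2)),
               ignore_attr = TRUE)

  expect_error(extract_brown_fat(pr, mask, extraction_spec(0)), "retain_fraction")
  empty <- apply_roi(ratio_matrix(vals, "full"), roi_mask(matrix(FALSE, h, w)))
  expect_error(extract_brown_fat(empty, roi_mask(matrix(FALSE, h, w))), "empty ROI")
})

test_that("extraction matches the stable-sort oracle and ignores out-of-ROI values", {
  for (seed in 1:8) {
    set.seed(seed)
    h <- 12; w <- 15
    vals <- matrix(sample(1:40, h * w, replace = TRUE) / 3, h, w)  # many ties
    in_roi <- matrix(runif(h * w) < 0.6, h, w)
    if (!any(in_roi)) in_roi[5, 5] <- TRUE
    mask <- suppressWarnings(roi_mask(in_roi))
    pr <- apply_roi(ratio_matrix(vals, "full"), mask)
    spec <- extraction_spec(0.05)
    ex <- extract_brown_fat(pr, mask, spec)
    k_expect <- ceiling(0.05 * sum(in_roi))
    expect_identical(ex$k, as.integer(k_expect))
    expect_identical(sum(ex$bprwo > 0) <= k_expect, TRUE)  # zeros may be retained
    expect_equal(unname(ex$retained_indices),
                 unname(oracle_extract_indices(vals, in_roi, k_expect)))

    # permuting out-of-ROI values cannot change the retained set
    vals2 <- vals
    out_idx <- which(!in_roi)
    vals2[out_idx] <- vals2[sample(out_idx)]
    ex2 <- extract_brown_fat(apply_roi(ratio_matrix(vals2, "full"), mask), mask, spec)
    expect_identical(ex$retained_indices, ex2$retained_indices)

    # sum of extraction equals sum of the k largest in-ROI values
    roi_sorted <- sort(vals[in_roi], decreasing = TRUE)
    expect_equal(sum(ex$bprwo), sum(roi_sorted[seq_len(k_expect)]))
  }
})

test_that("render_ratio_image spans the map's own range, constant maps render zero", {
  r <- ratio_matrix(matrix(c(0, 2, 5, 10), 2, 2), "full")
  img <- render_ratio_image(r)
  expect_identical(img[cbind(2, 2)], 255L)
  expect_identical(img[1, 1], 0L)

  two <- render_ratio_image(ratio_matrix(matrix(c(0, 10, 0, 10), 2, 2), "full"))
  expect_setequal(as.vector(two), c(0L, 255L))

  expect_warning(flat <- render_ratio_image(ratio_matrix(matrix(4, 3, 3), "full")),
                 "constant")
  expect_true(all(flat == 0L))
})

test_that("overlay_contours paints the stored paths and nothing else", {
  img <- eight_bit_image(matrix(77L, 9, 9))

  # hand-built mask object with empty contours -> pure triplication
  empty <- structure(list(in_roi = matrix(TRUE, 9, 9),
                          outer_contour = matrix(integer(0), 0, 2),
                          inner_contour = matrix(integer(0), 0, 2),
                          n_components = 1L), class = "RoiMask")
  ov <- overlay_contours(img, empty)
  expect_true(all(ov == 77L))

  one <- empty
  one$outer_contour <- cbind(4L, 6L)
  ov1 <- overlay_contours(img, one)
  expect_identical(ov1[4, 6, ], c(0L, 255L, 0L))
  ov1[4, 6, ] <- 77L
  expect_true(all(ov1 == 77L))

  # phantom annulus: green pixel set equals the stored outer path set
  sl <- generate_phantom_slice(tiny_params(seed = 5))
  base <- suppressWarnings(render_ratio_image(
    apply_roi(water_oil_ratio(sl$water, sl$fat), sl$mask)))
  ov2 <- overlay_contours(base, sl$mask)
  green <- which(ov2[, , 1] == 0L & ov2[, , 2] == 255L & ov2[, , 3] == 0L,
                 arr.ind = TRUE)
  expect_setequal(paste(green[, 1], green[, 2]),
                  paste(sl$mask$outer_contour[, 1], sl$mask$outer_contour[, 2]))
  red <- which(ov2[, , 1] == 255L & ov2[, , 2] == 0L & ov2[, , 3] == 0L,
               arr.ind = TRUE)
  expect_setequal(paste(red[, 1], red[, 2]),
                  paste(sl$mask$inner_contour[, 1], sl$mask$inner_contour[, 2]))

  expect_error(overlay_contours(img, roi_mask(matrix(TRUE, 4, 4))), "shape mismatch")
})

test_that("roi_mask traces closed contours consistent with the pixel set", {
  m <- matrix(FALSE, 15, 15); m[4:12, 4:12] <- TRUE; m[7:9, 7:9] <- FALSE
  rm <- roi_mask(m)
  expect_identical(rm$n_components, 1L)
  # outer path on ROI pixels, inner path on hole pixels
  expect_true(all(m[rm$outer_contour]))
  expect_true(all(!m[rm$inner_contour]))
  # closed: consecutive path points are 8-adjacent, including wrap-around
  d <- rbind(diff(rm$outer_contour), rm$outer_contour[1, ] -
               rm$outer_contour[nrow(rm$outer_contour), ])
  expect_true(all(abs(d) <= 1))

  # solid disk: no hole, no inner contour
  disk <- matrix(FALSE, 11, 11)
  disk[(row(disk) - 6)^2 + (col(disk) - 6)^2 <= 16] <- TRUE
  rd <- roi_mask(disk)
  expect_identical(nrow(rd$inner_contour), 0L)
  expect_gt(nrow(rd$outer_contour), 0L)
})
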