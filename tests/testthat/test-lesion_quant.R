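test_that("modal intensity estimation follows the histogram contract", {
  dm <- c(16, 16, 8)
  msk <- array(1L, dm)
  # delta distribution
  expect_equal(estimate_modal_intensity(array(100, dm), msk), 100)

  # bimodal: mode within one bin width of the dominant component
  set.seed(31)
  vals <- c(runif(1900, 99, 101), runif(148, 149, 151))
  img <- array(vals, dm)
  binw <- (max(vals) - min(vals)) / 256
  expect_lt(abs(estimate_modal_intensity(img, msk) - 100), binw + 1)

  # invariance to voxels outside the mask
  img2 <- img
  msk2 <- msk
  msk2[1:100] <- 0L
  img2[1:100] <- 1e6
  expect_equal(estimate_modal_intensity(img2, msk2),
               estimate_modal_intensity(img, msk2))

  expect_error(estimate_modal_intensity(img, array(0L, dm)), "empty")
  expect_error(estimate_modal_intensity(img, msk, n_bins = 1), "n_bins")
})

test_that("WMH segmentation thresholds strictly above k times the mode", {
  dm <- c(12, 12, 12)
  msk <- array(1L, dm)
  img <- array(100, dm)
  # constant image: nothing exceeds 1.40 x mode
  seg <- segment_wmh(img, msk)
  expect_equal(sum(seg$lesion_mask), 0)
  expect_equal(seg$total_volume, 0)

  # a voxel at exactly the threshold is excluded; just above is included.
  # range anchors at 50/150 keep the histogram bins (hence the mode estimate)
  # unchanged by the two probe voxels
  set.seed(30)
  img <- array(runif(prod(dm), 99.8, 100.2), dm)
  img[1] <- 50
  img[1000] <- 150
  thr <- 1.40 * estimate_modal_intensity(img, msk)
  img[2] <- thr
  img[3] <- thr + 1e-6
  seg2 <- segment_wmh(img, msk, k = 1.40)
  expect_equal(seg2$threshold, thr)
  expect_setequal(which(seg2$lesion_mask == 1L), c(3L, 1000L))

  # threshold monotonicity: larger k never enlarges the mask
  set.seed(32)
  img3 <- array(rlnorm(prod(dm), log(100), 0.3), dm)
  m_low <- segment_wmh(img3, msk, k = 1.2)$lesion_mask
  m_high <- segment_wmh(img3, msk, k = 1.6)$lesion_mask
  expect_true(all(m_high <= m_low))

  # idempotence / determinism
  expect_identical(segment_wmh(img3, msk)$lesion_mask,
                   segment_wmh(img3, msk)$lesion_mask)
  expect_error(segment_wmh(img3, array(0L, dm)), "empty")
})

test_that("planted phantom lesions are recovered voxel-exactly", {
  ph <- generate_phantom(phantom_spec(
    grid_shape = c(48, 48, 48), seed = 33,
    lesion_blobs = list(list(center = c(24, 24, 33), radius_mm = 6,
                             multiplier = 1.5),
                        list(center = c(14, 24, 24), radius_mm = 4,
                             multiplier = 2.0))))
  seg <- segment_wmh(ph$flair, ph$brain_mask, 1.40, ph$voxel_size)
  expect_identical(seg$lesion_mask, ph$lesion_mask)
  expect_gt(sum(seg$lesion_mask), 0)
})

test_that("PVH/DWMH partition matches an independent distance oracle", {
  ph <- generate_phantom(phantom_spec(
    grid_shape = c(48, 48, 48), seed = 34,
    lesion_blobs = list(list(center = c(24, 24, 31), radius_mm = 5,
                             multiplier = 1.6),
                        list(center = c(10, 24, 24), radius_mm = 4,
                             multiplier = 1.6))))
  seg <- segment_wmh(ph$flair, ph$brain_mask, 1.40, ph$voxel_size)
  seg <- partition_wmh(seg, ph$ventricle_mask, ph$atlas, pv_distance_mm = 10)

  # independent oracle: double loop over voxel centers
  vx <- ph$voxel_size
  les <- which(seg$lesion_mask == 1L)
  ven <- which(ph$ventricle_mask == 1L)
  lc <- arrayInd(les, dim(seg$lesion_mask))
  vc <- arrayInd(ven, dim(seg$lesion_mask))
  n_pvh <- 0
  for (i in seq_along(les)) {
    dmin <- Inf
    for (j in seq_along(ven)) {
      d <- sqrt(sum(((lc[i, ] - vc[j, ]) * vx)^2))
      if (d < dmin) dmin <- d
    }
    if (dmin <= 10) n_pvh <- n_pvh + 1
  }
  expect_equal(seg$pvh_volume, n_pvh * prod(vx))
  expect_equal(seg$pvh_volume + seg$dwmh_volume, seg$total_volume)
  expect_equal(sum(seg$lobar_volumes), seg$total_volume)

  # empty ventricle mask: everything is deep
  seg0 <- partition_wmh(seg, array(0L, dim(seg$lesion_mask)), ph$atlas)
  expect_equal(seg0$pvh_volume, 0)
  expect_equal(seg0$dwmh_volume, seg0$total_volume)

  # all lesions adjacent to ventricles: everything periventricular
  segv <- partition_wmh(seg, seg$lesion_mask, ph$atlas)
  expect_equal(segv$dwmh_volume, 0)
})

test_that("TIV normalization and square-root transform are exact and scale-free", {
  r <- normalize_and_transform(1e4, 1.45e6)
  expect_equal(r$normalized, 100 * 1e4 / 1.45e6)
  expect_equal(r$normalized, 0.6897, tolerance = 1e-4)
  expect_equal(r$transformed, sqrt(r$normalized))
  expect_equal(normalize_and_transform(0, 1e6), data.frame(normalized = 0,
                                                           transformed = 0))
  expect_equal(normalize_and_transform(2e4, 2.9e6),
               normalize_and_transform(1e4, 1.45e6))
  expect_error(normalize_and_transform(1, 0), "tiv")
  expect_error(normalize_and_transform(-1, 1), "volume")
})

test_that("manual edit masks override voxelwise and reset partitions", {
  dm <- c(10, 10, 10)
  img <- array(100, dm)
  img[1:5] <- 200
  seg <- segment_wmh(img, array(1L, dm))
  ed <- array(NA, dm)
  ed[1] <- 0    # remove one automatic voxel
  ed[100] <- 1  # add one
  expect_message(seg2 <- apply_edit_mask(seg, ed), "2 voxel")
  expect_equal(sum(seg2$lesion_mask), 5)
  expect_equal(seg2$lesion_mask[1], 0L)
  expect_equal(seg2$lesion_mask[100], 1L)
  expect_true(is.na(seg2$pvh_volume))
})
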