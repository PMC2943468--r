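test_that("reference stats use masked voxels only, with sample SD", {
  v <- vol_of(c(90, 100, 110))
  st <- compute_reference_stats(v, full_mask(v))
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 10)  # n - 1 denominator
  expect_equal(st$n_voxels, 3)

  const <- vol_of(rep(100, 8), dims = c(2, 2, 2))
  stc <- compute_reference_stats(const, full_mask(const))
  expect_equal(stc$mean, 100)
  expect_equal(stc$sd, 0)

  # mask restriction: extreme values outside the mask are invisible
  vals <- array(c(90, 100, 110, 1e6, -1e6, 1e6), dim = c(6, 1, 1))
  v2 <- image_volume(vals, unit_geometry(c(6, 1, 1)))
  m <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), dim = c(6, 1, 1))
  st2 <- compute_reference_stats(v2, region_mask("half", m))
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$sd, st$sd)

  expect_error(compute_reference_stats(v, region_mask(
    "empty", array(FALSE, dim = c(3, 1, 1)))), "at least 2")
})

test_that("thresholds sit exactly k sample SDs either side of the mean", {
  thr <- thr_from(100, 10, k = 4)
  expect_equal(thr$low, 60)
  expect_equal(thr$high, 140)
  expect_equal((thr$mean - thr$low) / thr$sd, 4)
  expect_equal((thr$high - thr$mean) / thr$sd, 4)

  degen <- thr_from(100, 0)
  expect_equal(degen$low, 100)
  expect_equal(degen$high, 100)

  st <- compute_reference_stats(vol_of(c(90, 100, 110)),
                                full_mask(vol_of(c(90, 100, 110))))
  expect_error(derive_thresholds(st, k = 0), "positive")
  expect_error(derive_thresholds(st, k = -2), "positive")
})

test_that("classification is three-class with neutral ties", {
  thr <- thr_from(100, 10)  # low 60, high 140
  v <- vol_of(c(59.999, 60, 100, 140, 140.001, 20, 200), dims = c(7, 1, 1))
  seg <- classify_voxels(v, full_mask(v), thr)
  expect_equal(as.integer(seg$labels), c(1L, 3L, 3L, 3L, 2L, 1L, 2L))
  expect_equal(seg$low_voxel_count, 2)
  expect_equal(seg$high_voxel_count, 2)
  # all voxels at the calibration mean: nothing classified
  flat <- vol_of(rep(100, 7), dims = c(7, 1, 1))
  seg0 <- classify_voxels(flat, full_mask(flat), thr)
  expect_equal(seg0$low_voxel_count, 0)
  expect_equal(seg0$high_voxel_count, 0)
  # outside the mask: unlabelled
  m <- array(c(TRUE, rep(FALSE, 6)), dim = c(7, 1, 1))
  segm <- classify_voxels(v, region_mask("one", m), thr)
  expect_equal(sum(segm$labels != 0L), 1)
})

test_that("noiseless phantom segmentation recovers the truth set exactly", {
  spec <- noiseless_spec(lesion_voxel_count = 1000L, n_clusters = 5L,
                         seed = 2L)
  pre <- generate_precontrast(spec)
  post <- generate_postcontrast(pre, spec)
  roi <- kidney_roi(pre$masks)
  thr <- derive_thresholds(compute_reference_stats(pre$volume, roi))
  seg <- classify_voxels(post$volume, roi, thr)
  expect_equal(seg$low_voxel_count, 1000)
  expect_identical(which(seg$labels == 1L), post$truth$lesion_voxels)
  # bright blood recovered as exactly the vessel set
  expect_identical(which(seg$labels == 2L), post$truth$vessel_voxels)
  expect_equal(contrast_volume(seg), post$truth$true_lesion_volume_um3)
})

test_that("classification is invariant to joint positive affine rescaling", {
  spec <- test_spec(lesion_voxel_count = 500L, seed = 13L)
  pre <- generate_precontrast(spec)
  post <- generate_postcontrast(pre, spec)
  roi <- kidney_roi(pre$masks)
  run <- function(pv, qv) {
    thr <- derive_thresholds(compute_reference_stats(pv, roi))
    classify_voxels(qv, roi, thr)$labels
  }
  base <- run(pre$volume, post$volume)
  a <- 2.7; b <- 13.1
  pre2 <- image_volume(a * pre$volume$data + b, spec$geometry)
  post2 <- image_volume(a * post$volume$data + b, spec$geometry)
  expect_identical(run(pre2, post2), base)
})

test_that("low count is non-increasing in the threshold multiplier k", {
  spec <- test_spec(lesion_voxel_count = 500L, seed = 19L)
  pre <- generate_precontrast(spec)
  post <- generate_postcontrast(pre, spec)
  roi <- kidney_roi(pre$masks)
  st <- compute_reference_stats(pre$volume, roi)
  counts <- vapply(c(1, 2, 3, 4, 6, 8), function(k) {
    classify_voxels(post$volume, roi, derive_thresholds(st, k))$low_voxel_count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("contrast volume uses the acquisition geometry in um^3", {
  # reference protocol: 100 x 100 x 229.17 um voxels
  g <- acquisition_geometry(c(25.6, 25.6, 22), c(256, 256, 96))
  expect_equal(voxel_volume_um3(g), 2291666.667, tolerance = 1e-9)
  thr <- thr_from(100, 10)
  mk_seg <- function(n_low, dims, geom) {
    vals <- array(100, dim = dims)
    vals[seq_len(n_low)] <- 0
    classify_voxels(image_volume(vals, geom),
                    region_mask("all", array(TRUE, dim = dims)), thr)
  }
  g64 <- acquisition_geometry(c(25.6, 25.6, 22), c(16, 16, 8))
  seg0 <- mk_seg(0, c(16, 16, 8), g64)
  expect_equal(contrast_volume(seg0), 0)
  seg1 <- mk_seg(100, c(16, 16, 8), g64)
  seg2 <- mk_seg(200, c(16, 16, 8), g64)
  expect_equal(contrast_volume(seg2), 2 * contrast_volume(seg1))  # linearity
  expect_equal(contrast_volume(seg1), 100 * voxel_volume_um3(g64))
})

test_that("zero-lesion noisy phantom yields a tiny false-positive fraction", {
  spec <- test_spec(lesion_voxel_count = 0L, seed = 23L)
  pre <- generate_precontrast(spec)
  post <- generate_postcontrast(pre, spec)
  roi <- kidney_roi(pre$masks)
  thr <- derive_thresholds(compute_reference_stats(pre$volume, roi))
  seg <- classify_voxels(post$volume, roi, thr)
  expect_lt(seg$low_voxel_count / seg$mask_voxel_count, 1e-3)
})

test_that("geometry and shape mismatches are rejected", {
  v <- vol_of(c(90, 100, 110))
  m <- region_mask("bad", array(TRUE, dim = c(2, 1, 1)))
  expect_error(compute_reference_stats(v, m), "shape")
  expect_error(classify_voxels(v, m, thr_from(100, 10)), "shape")
})
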