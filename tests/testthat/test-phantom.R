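test_that("geometry validates inputs and derives voxel volume", {
  g <- acquisition_geometry(c(25.6, 25.6, 22), c(256, 256, 96))
  expect_equal(voxel_size_um(g), c(100, 100, 22000 / 96))
  expect_equal(voxel_volume_um3(g), 100 * 100 * 22000 / 96)
  expect_error(acquisition_geometry(c(25.6, 25.6), c(256, 256, 96)),
               "length 3")
  expect_error(acquisition_geometry(c(25.6, 25.6, 0), c(256, 256, 96)),
               "positive")
  expect_error(acquisition_geometry(c(25.6, 25.6, 22), c(256, 0, 96)),
               ">= 1")
})

test_that("noiseless pre-contrast kidney is exactly the kidney mean", {
  spec <- noiseless_spec(kidney_mean = 100, seed = 7L)
  pre <- generate_precontrast(spec)
  expect_true(all(pre$volume$data[pre$masks$kidney$voxels] == 100))
  expect_true(all(pre$volume$data[pre$masks$vessel$voxels] ==
                    spec$vessel_intensity))
  expect_true(all(pre$volume$data[pre$masks$background$voxels] == 0))
})

test_that("same seed gives bit-identical volumes, different seeds differ", {
  spec <- test_spec(seed = 11L)
  a <- generate_precontrast(spec)
  b <- generate_precontrast(spec)
  expect_identical(a$volume$data, b$volume$data)
  pa <- generate_postcontrast(a, spec)
  pb <- generate_postcontrast(b, spec)
  expect_identical(pa$volume$data, pb$volume$data)
  expect_identical(pa$truth$lesion_voxels, pb$truth$lesion_voxels)
  spec2 <- test_spec(seed = 12L)
  expect_false(identical(generate_precontrast(spec2)$volume$data,
                         a$volume$data))
})

test_that("kidney texture reproduces the requested moments at large n", {
  spec <- test_spec(matrix_size = c(128L, 128L, 72L), kidney_mean = 100,
                    kidney_sd = 10, noise_sigma = 0, seed = 3L)
  pre <- generate_precontrast(spec)
  vals <- pre$volume$data[pre$masks$kidney$voxels]
  expect_gte(length(vals), 1e5)
  expect_lt(abs(mean(vals) - 100) / 100, 0.01)
  expect_lt(abs(sd(vals) - 10) / 10, 0.05)
})

test_that("organ masks are pairwise disjoint and non-empty", {
  pre <- generate_precontrast(test_spec(seed = 5L))
  m <- pre$masks
  nm <- names(m)
  for (i in seq_along(m)) {
    expect_gt(sum(m[[i]]$voxels), 0)
    for (j in seq_along(m)) {
      if (i < j) {
        expect_false(any(m[[i]]$voxels & m[[j]]$voxels),
                     info = paste(nm[i], "vs", nm[j]))
      }
    }
  }
})

test_that("degenerate or oversized requests are rejected", {
  expect_error(phantom_spec(geometry = acquisition_geometry(
    c(25.6, 25.6, 22), c(4, 4, 4))) |> generate_precontrast(),
    "grid too small")
  spec <- test_spec(matrix_size = c(16L, 16L, 8L),
                    lesion_voxel_count = 100000L)
  pre <- generate_precontrast(spec)
  expect_error(generate_postcontrast(pre, spec), "exceeds available")
  expect_warning(test_spec(lesion_intensity = 90), "not detectable")
})

test_that("post-contrast paints the exact lesion set and spares vessels", {
  spec <- noiseless_spec(lesion_voxel_count = 1000L, n_clusters = 5L,
                         seed = 21L)
  pre <- generate_precontrast(spec)
  post <- generate_postcontrast(pre, spec)
  truth <- post$truth
  expect_length(truth$lesion_voxels, 1000)
  expect_true(all(post$volume$data[truth$lesion_voxels] ==
                    spec$lesion_intensity))
  # lesions live inside the kidney parenchyma
  expect_true(all(pre$masks$kidney$voxels[truth$lesion_voxels]))
  # flowing blood is unaltered by bound contrast: verbatim copy
  vess <- pre$masks$vessel$voxels
  expect_identical(post$volume$data[vess], pre$volume$data[vess])
  # volume conservation is exact
  expect_identical(truth$true_lesion_volume_um3,
                   1000 * voxel_volume_um3(spec$geometry))
})

test_that("zero lesion count changes nothing but the noise draw", {
  spec <- test_spec(lesion_voxel_count = 0L, seed = 31L)
  pre <- generate_precontrast(spec)
  post <- generate_postcontrast(pre, spec)
  expect_length(post$truth$lesion_voxels, 0)
  expect_equal(post$truth$true_lesion_volume_um3, 0)
  # same scene, different realisation
  expect_false(identical(post$volume$data, pre$volume$data))
  kid <- pre$masks$kidney$voxels
  expect_lt(abs(mean(post$volume$data[kid]) - mean(pre$volume$data[kid])), 2)
})

test_that("truth clusters match the requested count under flood fill", {
  for (ncl in c(1L, 3L, 5L)) {
    spec <- noiseless_spec(lesion_voxel_count = 600L, n_clusters = ncl,
                           seed = 40L + ncl)
    post <- generate_postcontrast(generate_precontrast(spec), spec)
    comps <- flood_fill_components(post$truth$lesion_voxels,
                                   spec$geometry$matrix_size, 26)
    expect_length(comps, ncl)
    expect_equal(sum(lengths(comps)), 600)
  }
})

test_that("rician noise yields non-negative magnitudes with the right scale", {
  spec <- test_spec(noise_model = "rician", noise_sigma = 5, seed = 9L)
  pre <- generate_precontrast(spec)
  expect_true(all(pre$volume$data >= 0))
  # background magnitude mean of a Rayleigh(sigma) is sigma*sqrt(pi/2)
  bg <- pre$volume$data[pre$masks$background$voxels]
  expect_lt(abs(mean(bg) - 5 * sqrt(pi / 2)) / (5 * sqrt(pi / 2)), 0.15)
})

test_that("serial series has nested, saturating lesion growth", {
  kin <- kinetics_spec(timepoints_min = c(0, 30, 60, 90),
                       plateau_time_min = 60)
  spec <- test_spec(lesion_voxel_count = 800L, seed = 17L)
  ser <- generate_serial_series(spec, kin)
  counts <- vapply(ser, function(e) length(e$truth$lesion_voxels), numeric(1))
  expect_equal(counts[1], 0)              # pre-injection
  expect_true(all(diff(counts) >= 0))     # monotone binding
  expect_equal(counts[3], counts[4])      # stable after the plateau
  expect_equal(counts,
               round(800 * pmin(1, c(0, 30, 60, 90) / 60)))
  # nesting: earlier lesion sets are subsets of later ones
  for (i in 2:3) {
    expect_true(all(ser[[i]]$truth$lesion_voxels %in%
                      ser[[i + 1]]$truth$lesion_voxels))
  }
  # liver mean decays toward the floor
  liv <- attr(ser, "masks")$liver$voxels
  liver_means <- vapply(ser, function(e) mean(e$volume$data[liv]), numeric(1))
  expect_true(all(diff(liver_means) < 0))
})

test_that("kinetics spec rejects malformed time axes", {
  expect_error(kinetics_spec(timepoints_min = numeric(0)), "non-empty")
  expect_error(kinetics_spec(timepoints_min = c(0, 30, 30)),
               "strictly increasing")
  expect_error(kinetics_spec(timepoints_min = c(-5, 10)), "non-negative")
  kin <- kinetics_spec()
  expect_equal(bound_fraction(kin, c(0, 30, 60, 120)), c(0, 0.5, 1, 1))
})

test_that("paired expression is exactly linear at zero noise", {
  vols <- c(1, 2, 4, 8) * 1e9
  pairs <- generate_paired_expression(vols, slope = 2e-10, intercept = 0.3,
                                      noise_sd = 0, seed = 1L)
  expect_equal(pairs$mrna_rel_expression, 2e-10 * vols + 0.3)
  fit <- fit_linear(pairs$true_volume_um3, pairs$mrna_rel_expression)
  expect_equal(fit$slope, 2e-10, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  flat <- generate_paired_expression(vols, slope = 0, intercept = 0.7,
                                     noise_sd = 0, seed = 1L)
  expect_true(all(flat$mrna_rel_expression == 0.7))
  expect_error(generate_paired_expression(vols, 1, 0, noise_sd = -1),
               "non-negative")
  expect_error(generate_paired_expression(rep(1e9, 4), 1, 0),
               "distinct")
})

test_that("noisy regression recovers the slope within 3 SE almost always", {
  vols <- (1:12) * 1e8
  slope <- 1e-8; intercept <- 0.5
  hits <- vapply(1:500, function(s) {
    p <- generate_paired_expression(vols, slope, intercept,
                                    noise_sd = 0.5, seed = s)
    fit <- lm(p$mrna_rel_expression ~ p$true_volume_um3)
    se <- summary(fit)$coefficients[2, 2]
    abs(coef(fit)[2] - slope) <= 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
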