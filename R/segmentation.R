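#' Reference statistics of the pre-contrast kidney
#'
#' Mean and sample SD (n - 1 denominator) of the signal intensities inside
#' the kidney mask of the pre-contrast volume, pooled over the whole 3D
#' region. These calibrate the segmentation thresholds; the analysis never
#' consults absolute units, so calibration commutes with positive affine
#' rescaling of the data.
#'
#' @param pre Pre-contrast [image_volume()].
#' @param mask [region_mask()] of the kidney region (typically
#'   [kidney_roi()], which keeps the intrarenal vessels in the histogram).
#' @param per_slice If `TRUE`, also return a per-axial-slice table of
#'   mean/SD (whole-region pooling remains the calibration default).
#' @return An object of class `reference_stats` with elements `mean`, `sd`,
#'   `n_voxels` (and `per_slice` when requested).
#' @export
compute_reference_stats <- function(pre, mask, per_slice = FALSE) {
  stopifnot(inherits(pre, "image_volume"), inherits(mask, "region_mask"))
  check_congruent(pre, mask)
  n <- sum(mask$voxels)
  if (n < 2L) stop("calibration mask must contain at least 2 voxels")
  vals <- pre$data[mask$voxels]
  out <- structure(
    list(mean = mean(vals), sd = stats::sd(vals), n_voxels = n),
    class = "reference_stats"
  )
  if (per_slice) {
    nz <- dim(pre$data)[3]
    tab <- do.call(rbind, lapply(seq_len(nz), function(k) {
      m <- mask$voxels[, , k]
      if (!any(m)) return(NULL)
      v <- pre$data[, , k][m]
      data.frame(slice = k, n = length(v), mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }))
    out$per_slice <- tab
  }
  out
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("reference_stats: mean %.4g, sd %.4g over %d voxels\n",
              x$mean, x$sd, x$n_voxels))
  invisible(x)
}

#' Derive low/high segmentation thresholds
#'
#' Places the low-signal (bound iron-oxide contrast) and high-signal
#' (flowing blood) thresholds `k` standard deviations either side of the
#' pre-contrast kidney mean: `low = mean - k*sd`, `high = mean + k*sd`. The
#' default `k = 4` is the stringent calibration used for fully automated
#' segmentation; under pure Gaussian texture it admits a one-sided
#' false-positive fraction of about `pnorm(-4)` (3.17e-5).
#'
#' @param stats A [compute_reference_stats()] result.
#' @param k Positive unitless multiplier (default 4).
#' @return An object of class `threshold_pair` with elements `low`, `high`,
#'   `k`, `mean`, `sd`.
#' @export
derive_thresholds <- function(stats, k = 4) {
  stopifnot(inherits(stats, "reference_stats"))
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  structure(
    list(low = stats$mean - k * stats$sd,
         high = stats$mean + k * stats$sd,
         k = k, mean = stats$mean, sd = stats$sd),
    class = "threshold_pair"
  )
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("threshold_pair: low %.4g / high %.4g (mean %.4g +/- %g sd)\n",
              x$low, x$high, x$mean, x$k))
  invisible(x)
}

#' Classify post-contrast voxels into low / high / neutral
#'
#' Within the mask, a voxel strictly below the low threshold is labelled
#' `low` (contrast effect), strictly above the high threshold `high`
#' (bright blood), and otherwise `neutral`; ties at a threshold are neutral
#' ("either side of" the band). Voxels outside the mask are unlabelled.
#' Classified voxel counts are converted to physical volumes via the
#' acquisition geometry.
#'
#' The thresholds must have been calibrated on the same animal's
#' pre-contrast scan in the same frame; the caller's calibration provenance
#' is recorded in the result. Pre and post volumes are assumed voxel-aligned
#' (fixed-cradle acquisition); a geometry check guards this.
#'
#' @param post Post-contrast [image_volume()].
#' @param mask [region_mask()] restricting classification (same region the
#'   thresholds were calibrated on).
#' @param thr A [derive_thresholds()] result.
#' @return An object of class `segmentation_result`: integer label array
#'   (0 = outside mask, 1 = low, 2 = high, 3 = neutral), voxel counts,
#'   volumes in um^3, the thresholds, and the geometry.
#' @export
classify_voxels <- function(post, mask, thr) {
  stopifnot(inherits(post, "image_volume"), inherits(mask, "region_mask"),
            inherits(thr, "threshold_pair"))
  check_congruent(post, mask)
  labels <- array(0L, dim = dim(post$data))
  m <- mask$voxels
  vals <- post$data[m]
  cls <- rep(3L, length(vals))
  cls[vals < thr$low] <- 1L
  cls[vals > thr$high] <- 2L
  labels[m] <- cls
  vv3 <- voxel_volume_um3(post$geometry)
  low_n <- sum(cls == 1L)
  high_n <- sum(cls == 2L)
  structure(
    list(
      labels = labels,
      low_voxel_count = low_n, high_voxel_count = high_n,
      low_volume_um3 = low_n * vv3, high_volume_um3 = high_n * vv3,
      thresholds = thr, geometry = post$geometry,
      mask_name = mask$name, mask_voxel_count = sum(m)
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation_result: %d low (%.4g um^3), %d high (%.4g um^3) of %d voxels in '%s'\n",
    x$low_voxel_count, x$low_volume_um3,
    x$high_voxel_count, x$high_volume_um3,
    x$mask_voxel_count, x$mask_name
  ))
  invisible(x)
}

#' Total contrast volume of a segmentation
#'
#' The summed physical volume of all low-signal (contrast) voxels, in um^3:
#' `low_voxel_count * (fov_x/nx) * (fov_y/ny) * (fov_z/nz)`.
#'
#' @param result A [classify_voxels()] result.
#' @return Single number, um^3.
#' @export
contrast_volume <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  result$low_volume_um3
}

#' Write a segmentation result to disk
#'
#' Writes the 3-class label volume as integer NIfTI plus a JSON report with
#' counts, volumes, thresholds and calibration provenance.
#'
#' @param result A [classify_voxels()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_segmentation <- function(result, dir, prefix = "segmentation") {
  stopifnot(inherits(result, "segmentation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  label_path <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  img <- RNifti::asNifti(result$labels)
  RNifti::pixdim(img) <- result$geometry$fov_mm / result$geometry$matrix_size
  RNifti::writeNifti(img, label_path)
  report <- list(
    low_voxel_count = result$low_voxel_count,
    high_voxel_count = result$high_voxel_count,
    low_volume_um3 = result$low_volume_um3,
    high_volume_um3 = result$high_volume_um3,
    voxel_volume_um3 = voxel_volume_um3(result$geometry),
    thresholds = list(low = result$thresholds$low,
                      high = result$thresholds$high,
                      k = result$thresholds$k,
                      calibration_mean = result$thresholds$mean,
                      calibration_sd = result$thresholds$sd),
    mask = list(name = result$mask_name,
                voxel_count = result$mask_voxel_count)
  )
  report_path <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  invisible(c(labels = label_path, report = report_path))
}
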