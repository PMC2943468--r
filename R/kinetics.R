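#' Organ signal-to-noise ratio
#'
#' SNR of an organ region: mean signal intensity over the organ mask divided
#' by the standard deviation of the intensities in a background-noise region
#' (air outside the animal). SNR is invariant to multiplying all intensities
#' by a positive constant; an additive offset shifts the numerator only, and
#' therefore shifts SNR by `offset / noise_sd`.
#'
#' @param vol An [image_volume()].
#' @param organ [region_mask()] of the organ of interest.
#' @param noise_region [region_mask()] of the background-noise region;
#'   must be disjoint from `organ`.
#' @return Single unitless number.
#' @export
organ_snr <- function(vol, organ, noise_region) {
  stopifnot(inherits(vol, "image_volume"),
            inherits(organ, "region_mask"),
            inherits(noise_region, "region_mask"))
  check_congruent(vol, organ)
  check_congruent(vol, noise_region)
  if (!any(organ$voxels)) stop("organ mask is empty")
  if (sum(noise_region$voxels) < 2L) stop("noise region must have >= 2 voxels")
  if (any(organ$voxels & noise_region$voxels)) {
    stop("organ and noise-region masks must be disjoint")
  }
  noise_sd <- stats::sd(vol$data[noise_region$voxels])
  if (noise_sd == 0) stop("noise region has zero standard deviation")
  mean(vol$data[organ$voxels]) / noise_sd
}

#' Earliest plateau time of a contrast-volume series
#'
#' The plateau is the earliest time point after which every subsequent
#' relative change in low-signal volume is below `rel_tol`. Changes are
#' measured relative to the series maximum so that a zero baseline (the
#' pre-injection scan) is handled cleanly. If the series is still changing
#' at the end, the last time point is returned with `reached = FALSE`.
#'
#' @param times_min Strictly increasing times in minutes.
#' @param volumes_um3 Low-signal volumes at those times.
#' @param rel_tol Relative-change tolerance (default 0.05).
#' @return List with `time_min` and `reached`.
#' @export
plateau_time <- function(times_min, volumes_um3, rel_tol = 0.05) {
  if (length(times_min) != length(volumes_um3)) {
    stop("times and volumes must have equal length")
  }
  if (length(times_min) < 2L) stop("need >= 2 time points")
  if (is.unsorted(times_min, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  ref <- max(abs(volumes_um3))
  if (ref == 0) return(list(time_min = times_min[1], reached = TRUE))
  rel_change <- abs(diff(volumes_um3)) / ref
  stable <- rel_change < rel_tol
  # earliest index i such that all changes from i onward are stable
  n <- length(times_min)
  suffix_ok <- rev(cumprod(rev(stable))) == 1
  if (any(suffix_ok)) {
    list(time_min = times_min[which(suffix_ok)[1]], reached = TRUE)
  } else {
    list(time_min = times_min[n], reached = FALSE)
  }
}

#' Summarize a serial imaging experiment
#'
#' Collects the contrast-volume time course and per-organ SNR series, and
#' reports the earliest plateau time of the contrast volume.
#'
#' @param serial A list with one entry per time point; each entry must have
#'   `time_min`, a `result` ([classify_voxels()] output), and optionally a
#'   named numeric vector `snr` of per-organ SNR values.
#' @param rel_tol Plateau tolerance passed to [plateau_time()].
#' @return An object of class `kinetics_summary`: `contrast_series`
#'   (data.frame time_min, low_volume_um3), `snr_series` (data.frame
#'   time_min, organ, snr; may be empty), `time_to_plateau_min`,
#'   `plateau_reached`.
#' @export
summarize_kinetics <- function(serial, rel_tol = 0.05) {
  if (length(serial) < 2L) stop("need >= 2 time points")
  times <- vapply(serial, function(e) as.numeric(e$time_min), numeric(1))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("serial entries must be in strictly increasing time order")
  }
  vols <- vapply(serial, function(e) {
    stopifnot(inherits(e$result, "segmentation_result"))
    e$result$low_volume_um3
  }, numeric(1))
  snr_rows <- lapply(seq_along(serial), function(i) {
    s <- serial[[i]]$snr
    if (is.null(s)) return(NULL)
    data.frame(time_min = times[i], organ = names(s), snr = as.numeric(s),
               row.names = NULL)
  })
  snr_series <- do.call(rbind, snr_rows)
  if (is.null(snr_series)) {
    snr_series <- data.frame(time_min = numeric(0), organ = character(0),
                             snr = numeric(0))
  }
  pl <- plateau_time(times, vols, rel_tol)
  structure(
    list(
      contrast_series = data.frame(time_min = times, low_volume_um3 = vols),
      snr_series = snr_series,
      time_to_plateau_min = pl$time_min,
      plateau_reached = pl$reached,
      rel_tol = rel_tol
    ),
    class = "kinetics_summary"
  )
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf(
    "kinetics_summary: %d time points, plateau at %g min (%s)\n",
    nrow(x$contrast_series), x$time_to_plateau_min,
    if (x$plateau_reached) "reached" else "not reached"
  ))
  invisible(x)
}
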