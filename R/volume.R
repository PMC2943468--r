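#' 3D image volume
#'
#' A 3D grid of scalar signal intensities (arbitrary units) tied to an
#' [acquisition_geometry()]. The array dimensions must equal the acquisition
#' matrix, and every intensity must be finite. Intensities carry no absolute
#' unit: all downstream logic (threshold calibration, classification, SNR) is
#' invariant to positive affine rescaling of the data.
#'
#' @param data 3D numeric array of intensities.
#' @param geometry An [acquisition_geometry()] whose matrix matches `dim(data)`.
#'
#' @return An object of class `image_volume` with elements `data`, `geometry`.
#' @export
image_volume <- function(data, geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3D array")
  }
  if (!identical(dim(data), as.integer(geometry$matrix_size))) {
    stop("array dimensions do not match the acquisition matrix")
  }
  if (!all(is.finite(data))) stop("all intensities must be finite")
  structure(list(data = data, geometry = geometry), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_volume: %d x %d x %d voxels, intensity range [%.4g, %.4g]\n",
    d[1], d[2], d[3], min(x$data), max(x$data)
  ))
  invisible(x)
}

#' Named boolean region mask
#'
#' Marks the voxels of an [image_volume()] belonging to a named region
#' (kidney, vessel, liver, background-noise region, ...). The mask grid must
#' be congruent with the volume it describes.
#'
#' @param name Region label (single string).
#' @param voxels 3D logical array; `TRUE` marks membership.
#'
#' @return An object of class `region_mask` with elements `name`, `voxels`.
#' @export
region_mask <- function(name, voxels) {
  if (!is.character(name) || length(name) != 1L) stop("name must be a string")
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels)) {
    stop("voxels must be a 3D logical array")
  }
  if (anyNA(voxels)) stop("mask must not contain NA")
  structure(list(name = name, voxels = voxels), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask '%s': %d voxels\n", x$name, sum(x$voxels)))
  invisible(x)
}

check_congruent <- function(vol, mask) {
  if (!identical(dim(vol$data), dim(mask$voxels))) {
    stop(sprintf("mask '%s' shape does not match the volume", mask$name))
  }
  invisible(TRUE)
}

#' Combined kidney region of interest
#'
#' The manually-masked kidney border encloses both parenchyma and the
#' intrarenal vessel tree; threshold calibration and classification operate
#' on this union by default (the bright renal-artery peak sits inside the
#' pre-contrast histogram). Pass `include_vessel = FALSE` to calibrate on
#' parenchyma alone.
#'
#' @param masks Named list of [region_mask()] objects containing at least
#'   `kidney`, and `vessel` when `include_vessel` is `TRUE`.
#' @param include_vessel Include the vessel voxels in the ROI (default TRUE).
#' @return A [region_mask()] named `"kidney_roi"`.
#' @export
kidney_roi <- function(masks, include_vessel = TRUE) {
  vox <- masks$kidney$voxels
  if (include_vessel) vox <- vox | masks$vessel$voxels
  region_mask("kidney_roi", vox)
}

#' Read / write image volumes as NIfTI
#'
#' Volumes are written as NIfTI-1 with the voxel dimensions (mm) recorded in
#' the header, so physical geometry round-trips. Masks are written as integer
#' label volumes (0/1).
#'
#' @param vol An [image_volume()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   [image_volume()] with geometry reconstructed from the header.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$geometry$fov_mm / vol$geometry$matrix_size
  RNifti::pixunits(img) <- "mm"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D NIfTI volume")
  pd <- RNifti::pixdim(img)[seq_len(3)]
  geom <- acquisition_geometry(pd * d, d)
  image_volume(array(as.numeric(img), dim = d), geom)
}

#' @rdname write_volume
#' @param mask A [region_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim = dim(mask$voxels)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an image volume as a multi-page TIFF stack
#'
#' One grayscale page per axial (z) slice; intensities are rescaled to
#' `[0, 1]` for storage, so TIFF export is for visualisation, not analysis.
#' Requires the `tiff` package.
#'
#' @param vol An [image_volume()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  d <- dim(vol$data)
  rng <- range(vol$data)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(d[3]), function(k) {
    (vol$data[, , k] - rng[1]) / scale
  })
  tiff::writeTIFF(pages, path)
  invisible(path)
}
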