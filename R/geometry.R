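#' Acquisition geometry of a 3D MR volume
#'
#' Couples the physical field of view (FOV, in mm) to the acquisition matrix
#' (voxel counts per axis). All physical volume computations in the package
#' derive from this pairing: the voxel size along each axis is `fov_mm /
#' matrix_size`.
#'
#' @param fov_mm Numeric length-3 vector of physical extents (x, y, z) in mm.
#' @param matrix_size Integer length-3 vector of voxel counts (nx, ny, nz).
#'
#' @return An object of class `acquisition_geometry` with elements `fov_mm`
#'   and `matrix_size`.
#' @examples
#' g <- acquisition_geometry(c(25.6, 25.6, 22), c(256, 256, 96))
#' voxel_volume_um3(g)
#' @export
acquisition_geometry <- function(fov_mm, matrix_size) {
  fov_mm <- as.numeric(fov_mm)
  matrix_size <- as.integer(matrix_size)
  if (length(fov_mm) != 3L || length(matrix_size) != 3L) {
    stop("fov_mm and matrix_size must each have length 3")
  }
  if (any(!is.finite(fov_mm)) || any(fov_mm <= 0)) {
    stop("all field-of-view extents must be positive and finite")
  }
  if (any(is.na(matrix_size)) || any(matrix_size < 1L)) {
    stop("all matrix dimensions must be >= 1")
  }
  structure(
    list(fov_mm = fov_mm, matrix_size = matrix_size),
    class = "acquisition_geometry"
  )
}

#' Default acquisition geometry
#'
#' The 3D gradient-echo geometry used throughout as the reference protocol:
#' 25.6 x 25.6 x 22 mm field of view at a 256 x 256 x 96 matrix, giving
#' 100 x 100 x 229.17 um voxels (~2.292e6 um^3 per voxel).
#'
#' @return An [acquisition_geometry()] object.
#' @export
default_geometry <- function() {
  acquisition_geometry(c(25.6, 25.6, 22), c(256L, 256L, 96L))
}

#' Voxel dimensions in micrometres
#'
#' @param geometry An [acquisition_geometry()] object.
#' @return Numeric length-3 vector of voxel edge lengths in um.
#' @export
voxel_size_um <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  1000 * geometry$fov_mm / geometry$matrix_size
}

#' Voxel volume in cubic micrometres
#'
#' @param geometry An [acquisition_geometry()] object.
#' @return Single number: the physical volume of one voxel in um^3.
#' @export
voxel_volume_um3 <- function(geometry) {
  prod(voxel_size_um(geometry))
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "acquisition_geometry: FOV %g x %g x %g mm, matrix %d x %d x %d (voxel %.4g um^3)\n",
    x$fov_mm[1], x$fov_mm[2], x$fov_mm[3],
    x$matrix_size[1], x$matrix_size[2], x$matrix_size[3],
    voxel_volume_um3(x)
  ))
  invisible(x)
}

geometry_equal <- function(a, b) {
  isTRUE(all.equal(a$fov_mm, b$fov_mm)) &&
    identical(a$matrix_size, b$matrix_size)
}
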