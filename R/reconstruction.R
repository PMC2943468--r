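#' Two-channel 3D overlay of a segmentation
#'
#' Maps the 3-class labelling to the two-channel rendering convention used
#' for 3D reconstruction: low-signal (contrast) voxels to the green channel
#' and high-signal (bright blood) voxels to the red channel. The channels
#' are disjoint by construction.
#'
#' @param result A [classify_voxels()] result.
#' @return An object of class `overlay_volume` with logical arrays
#'   `green_channel`, `red_channel` and the `geometry`.
#' @export
build_overlay <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  structure(
    list(
      green_channel = result$labels == 1L,
      red_channel = result$labels == 2L,
      geometry = result$geometry
    ),
    class = "overlay_volume"
  )
}

#' @export
print.overlay_volume <- function(x, ...) {
  cat(sprintf("overlay_volume: %d green (contrast), %d red (blood) voxels\n",
              sum(x$green_channel), sum(x$red_channel)))
  invisible(x)
}

# Edges between foreground voxels under 6/18/26-connectivity, built by
# shifting linear indices once per symmetric offset (vectorised).
.voxel_edges <- function(fg, connectivity) {
  d <- dim(fg)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  offs <- offs[keep, , drop = FALSE]
  # one of each symmetric pair
  offs <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & (offs[, 2] > 0 |
                                      (offs[, 2] == 0 & offs[, 1] > 0))),
               , drop = FALSE]
  idx <- which(fg)
  if (length(idx) == 0L) return(matrix(integer(0), ncol = 2))
  co <- arrayInd(idx, d)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ti <- co[, 1] + o[1]; tj <- co[, 2] + o[2]; tk <- co[, 3] + o[3]
    ok <- ti >= 1 & ti <= nx & tj >= 1 & tj <= ny & tk >= 1 & tk <= nz
    tgt <- ti[ok] + nx * (tj[ok] - 1L) + nx * ny * (tk[ok] - 1L)
    hit <- fg[tgt]
    edges[[r]] <- cbind(idx[ok][hit], tgt[hit])
  }
  do.call(rbind, edges)
}

#' Label connected components of the contrast (green) channel
#'
#' Standard 3D connected-component labelling at 6, 18 or 26 connectivity
#' (default 26: clusters of bound particles appear as diagonally touching
#' voxel runs). Components are summarised with voxel count, physical volume
#' and centroid in physical mm coordinates (voxel-centre convention:
#' component volumes always sum to the total low-signal volume).
#'
#' @param overlay A [build_overlay()] result, or a [classify_voxels()]
#'   result (converted internally).
#' @param connectivity One of 6, 18, 26.
#' @return A data.frame with columns `component_id`, `voxel_count`,
#'   `volume_um3`, `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`,
#'   ordered by decreasing voxel count.
#' @export
label_components <- function(overlay, connectivity = 26) {
  if (inherits(overlay, "segmentation_result")) {
    overlay <- build_overlay(overlay)
  }
  stopifnot(inherits(overlay, "overlay_volume"))
  if (!connectivity %in% c(6, 18, 26)) {
    stop("connectivity must be 6, 18 or 26")
  }
  fg <- overlay$green_channel
  idx <- which(fg)
  empty <- data.frame(
    component_id = integer(0), voxel_count = integer(0),
    volume_um3 = numeric(0), centroid_x_mm = numeric(0),
    centroid_y_mm = numeric(0), centroid_z_mm = numeric(0)
  )
  if (length(idx) == 0L) return(empty)
  edges <- .voxel_edges(fg, connectivity)
  verts <- as.character(idx)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1]),
                   to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = verts)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[verts]

  d <- dim(fg)
  vs_mm <- overlay$geometry$fov_mm / overlay$geometry$matrix_size
  vv3 <- voxel_volume_um3(overlay$geometry)
  co <- arrayInd(idx, d)
  # voxel-centre physical coordinates
  px <- (co[, 1] - 0.5) * vs_mm[1]
  py <- (co[, 2] - 0.5) * vs_mm[2]
  pz <- (co[, 3] - 0.5) * vs_mm[3]
  tab <- data.frame(
    member = as.integer(membership),
    px = px, py = py, pz = pz
  )
  agg <- do.call(rbind, lapply(split(tab, tab$member), function(s) {
    data.frame(voxel_count = nrow(s),
               centroid_x_mm = mean(s$px),
               centroid_y_mm = mean(s$py),
               centroid_z_mm = mean(s$pz))
  }))
  agg <- agg[order(-agg$voxel_count), , drop = FALSE]
  out <- data.frame(
    component_id = seq_len(nrow(agg)),
    voxel_count = agg$voxel_count,
    volume_um3 = agg$voxel_count * vv3,
    centroid_x_mm = agg$centroid_x_mm,
    centroid_y_mm = agg$centroid_y_mm,
    centroid_z_mm = agg$centroid_z_mm
  )
  rownames(out) <- NULL
  out
}

#' Export an overlay volume
#'
#' Writes a label NIfTI (0 background, 1 green/contrast, 2 red/blood) and,
#' when the `tiff` package is available and `tiff = TRUE`, an RGB multi-page
#' TIFF stack (one page per axial slice).
#'
#' @param overlay A [build_overlay()] result.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @param tiff Also write the RGB TIFF stack.
#' @return Named character vector of written paths, invisibly.
#' @export
write_overlay <- function(overlay, dir, prefix = "overlay", tiff = FALSE) {
  stopifnot(inherits(overlay, "overlay_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- array(0L, dim = dim(overlay$green_channel))
  lab[overlay$green_channel] <- 1L
  lab[overlay$red_channel] <- 2L
  nii_path <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- overlay$geometry$fov_mm / overlay$geometry$matrix_size
  RNifti::writeNifti(img, nii_path)
  paths <- c(labels = nii_path)
  if (tiff) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF export")
    }
    d <- dim(lab)
    pages <- lapply(seq_len(d[3]), function(k) {
      rgb <- array(0, dim = c(d[1], d[2], 3))
      rgb[, , 1] <- overlay$red_channel[, , k]
      rgb[, , 2] <- overlay$green_channel[, , k]
      rgb
    })
    tif_path <- file.path(dir, paste0(prefix, "_rgb.tif"))
    tiff::writeTIFF(pages, tif_path)
    paths <- c(paths, rgb = tif_path)
  }
  invisible(paths)
}
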