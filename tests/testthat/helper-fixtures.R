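# Shared fixtures: all built in code at test time.

# Geometry whose voxels are 1 mm cubes, handy for exact volume arithmetic.
unit_geometry <- function(dims) {
  acquisition_geometry(fov_mm = dims, matrix_size = dims)
}

# Wrap a numeric vector/array as an image_volume (1 mm cubic voxels).
vol_of <- function(values, dims = NULL) {
  if (is.null(dims)) dims <- c(length(values), 1L, 1L)
  image_volume(array(values, dim = dims), unit_geometry(dims))
}

full_mask <- function(vol, name = "all") {
  region_mask(name, array(TRUE, dim = dim(vol$data)))
}

# Threshold pair calibrated from a three-voxel region with exactly the
# requested sample mean and SD: values (m - s, m, m + s).
thr_from <- function(mean, sd, k = 4) {
  v <- vol_of(c(mean - sd, mean, mean + sd))
  derive_thresholds(compute_reference_stats(v, full_mask(v)), k = k)
}

# Small reduced-grid phantom spec used across tests.
test_spec <- function(matrix_size = c(64L, 64L, 24L), ...) {
  phantom_spec(
    geometry = acquisition_geometry(c(25.6, 25.6, 22), matrix_size),
    ...
  )
}

noiseless_spec <- function(...) {
  test_spec(kidney_sd = 0, noise_sigma = 0, ...)
}

# Independent connected-component oracle: plain queue-based flood fill over
# a set of linear voxel indices. Deliberately naive; shares no code with the
# package's labelling path.
flood_fill_components <- function(idx, dims, connectivity = 26) {
  if (length(idx) == 0L) return(list())
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[ord == 1, , drop = FALSE],
                 "18" = offs[ord >= 1 & ord <= 2, , drop = FALSE],
                 "26" = offs[ord >= 1, , drop = FALSE])
  inset <- array(FALSE, dim = dims)
  inset[idx] <- TRUE
  visited <- array(FALSE, dim = dims)
  comps <- list()
  for (start in idx) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      cv <- arrayInd(v, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- cv + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        li <- nb[1] + dims[1] * (nb[2] - 1L) + dims[1] * dims[2] * (nb[3] - 1L)
        if (inset[li] && !visited[li]) {
          visited[li] <- TRUE
          queue <- c(queue, li)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}
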