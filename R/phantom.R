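#' Synthetic renal phantom specification
#'
#' Parameters of a synthetic pre/post-contrast scene: a kidney compartment
#' with approximately Gaussian signal texture, a bright intrarenal vessel
#' tree (bright-blood imaging), a liver compartment, an air background used
#' as the noise region, and dark lesion clusters painted at a known voxel
#' count — the ground truth for volumetric recovery. Intensities are in
#' arbitrary units; only their relative arrangement matters downstream.
#'
#' A spec is "detectable" when `lesion_intensity < kidney_mean - 4*kidney_sd`
#' and `vessel_intensity > kidney_mean + 4*kidney_sd`, i.e. when lesions and
#' vessels sit outside the 4-SD calibration band of the kidney texture. A
#' non-detectable spec is accepted but flagged with a warning.
#'
#' @param geometry An [acquisition_geometry()]; defaults to the 25.6 x 25.6 x
#'   22 mm, 256 x 256 x 96 reference protocol.
#' @param kidney_mean Mean kidney signal (arbitrary units).
#' @param kidney_sd SD of the Gaussian kidney texture.
#' @param vessel_intensity Signal of flowing blood (must sit far above
#'   `kidney_mean` for bright-blood segmentation).
#' @param lesion_intensity Signal of bound iron-oxide contrast (far below
#'   `kidney_mean`; T2* signal void).
#' @param lesion_voxel_count Number of lesion voxels to paint post-contrast.
#' @param n_clusters Number of contiguous lesion clusters the voxels are
#'   divided into.
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude of a
#'   complex Gaussian channel pair, as in magnitude-reconstructed MR data).
#' @param noise_sigma Acquisition noise level (per channel for rician).
#' @param liver_mean Baseline liver signal before contrast clearance.
#' @param seed Integer seed; all generators are bit-reproducible given the
#'   spec seed.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = default_geometry(),
                         kidney_mean = 100,
                         kidney_sd = 10,
                         vessel_intensity = 250,
                         lesion_intensity = 10,
                         lesion_voxel_count = 1000L,
                         n_clusters = 5L,
                         noise_model = c("gaussian", "rician"),
                         noise_sigma = 5,
                         liver_mean = 150,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    inherits(geometry, "acquisition_geometry"),
    is.finite(kidney_mean), is.finite(vessel_intensity),
    is.finite(lesion_intensity), is.finite(liver_mean),
    is.finite(kidney_sd), kidney_sd >= 0,
    is.finite(noise_sigma), noise_sigma >= 0,
    length(seed) == 1L, is.finite(seed)
  )
  lesion_voxel_count <- as.integer(lesion_voxel_count)
  n_clusters <- as.integer(n_clusters)
  if (is.na(lesion_voxel_count) || lesion_voxel_count < 0L) {
    stop("lesion_voxel_count must be a non-negative integer")
  }
  if (is.na(n_clusters) || n_clusters < 1L) stop("n_clusters must be >= 1")
  detectable <- (lesion_intensity < kidney_mean - 4 * kidney_sd) &&
    (vessel_intensity > kidney_mean + 4 * kidney_sd)
  if (!detectable) {
    warning("phantom spec is not detectable at k = 4: lesion or vessel ",
            "intensity lies inside the 4-SD band of the kidney texture")
  }
  structure(
    list(
      geometry = geometry, kidney_mean = kidney_mean, kidney_sd = kidney_sd,
      vessel_intensity = vessel_intensity, lesion_intensity = lesion_intensity,
      lesion_voxel_count = lesion_voxel_count, n_clusters = n_clusters,
      noise_model = noise_model, noise_sigma = noise_sigma,
      liver_mean = liver_mean, seed = as.integer(seed),
      detectable = detectable
    ),
    class = "phantom_spec"
  )
}

#' Binding and clearance kinetics specification
#'
#' Describes the serial time course emulated by [generate_serial_series()]:
#' the bound fraction of contrast rises with a piecewise-linear saturation
#' `min(1, t / plateau_time_min)` and is constant after `plateau_time_min`,
#' while the liver signal decays exponentially toward a floor with time
#' constant `liver_decay_tau_min` as unbound particles are sequestered.
#'
#' @param timepoints_min Strictly increasing, non-negative imaging times in
#'   minutes post-injection.
#' @param plateau_time_min Time at which binding saturates (default 60 min).
#' @param uptake_t50_min Time to half-maximal bound fraction. Under the
#'   default linear saturation this is `plateau_time_min / 2`; the field is
#'   validated and recorded for provenance.
#' @param liver_decay_tau_min Exponential time constant of liver signal decay.
#' @param liver_floor Asymptotic liver signal after clearance.
#'
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(timepoints_min = c(0, 30, 60, 90),
                          plateau_time_min = 60,
                          uptake_t50_min = plateau_time_min / 2,
                          liver_decay_tau_min = 15,
                          liver_floor = 40) {
  timepoints_min <- as.numeric(timepoints_min)
  if (length(timepoints_min) == 0L) stop("timepoints_min must be non-empty")
  if (any(!is.finite(timepoints_min)) || any(timepoints_min < 0)) {
    stop("timepoints must be finite and non-negative")
  }
  if (is.unsorted(timepoints_min, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  stopifnot(
    plateau_time_min > 0, liver_decay_tau_min > 0,
    uptake_t50_min > 0, uptake_t50_min <= plateau_time_min,
    is.finite(liver_floor)
  )
  structure(
    list(
      timepoints_min = timepoints_min, plateau_time_min = plateau_time_min,
      uptake_t50_min = uptake_t50_min,
      liver_decay_tau_min = liver_decay_tau_min, liver_floor = liver_floor
    ),
    class = "kinetics_spec"
  )
}

#' Bound fraction of contrast at a given time
#'
#' Piecewise-linear saturation: `min(1, t / plateau_time_min)`. Non-decreasing
#' in `t`, 0 at injection, 1 at and after the plateau.
#'
#' @param kin A [kinetics_spec()].
#' @param t_min Time(s) in minutes post-injection.
#' @return Numeric vector of bound fractions in `[0, 1]`.
#' @export
bound_fraction <- function(kin, t_min) {
  stopifnot(inherits(kin, "kinetics_spec"))
  pmin(1, pmax(0, t_min) / kin$plateau_time_min)
}

# Deterministic organ layout derived purely from the grid size: kidney and
# liver ellipsoids, a thin vessel tree inside the kidney, and an air box in
# one corner used as the background-noise region. Masks are pairwise disjoint.
.organ_masks <- function(geometry) {
  d <- geometry$matrix_size
  if (any(d < 8L)) stop("grid too small for the organ layout (need >= 8 per axis)")
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ii <- slice.index(array(0, dim = d), 1)
  jj <- slice.index(array(0, dim = d), 2)
  kk <- slice.index(array(0, dim = d), 3)

  kid_c <- c(0.32 * nx, 0.50 * ny, 0.50 * nz)
  kid_r <- c(0.22 * nx, 0.30 * ny, 0.32 * nz)
  kidney <- ((ii - kid_c[1]) / kid_r[1])^2 +
    ((jj - kid_c[2]) / kid_r[2])^2 +
    ((kk - kid_c[3]) / kid_r[3])^2 <= 1

  liv_c <- c(0.76 * nx, 0.38 * ny, 0.50 * nz)
  liv_r <- c(0.16 * nx, 0.22 * ny, 0.28 * nz)
  liver <- ((ii - liv_c[1]) / liv_r[1])^2 +
    ((jj - liv_c[2]) / liv_r[2])^2 +
    ((kk - liv_c[3]) / liv_r[3])^2 <= 1

  vessel <- .vessel_tree(d, kid_c, kid_r)
  vessel <- vessel & kidney

  bg <- array(FALSE, dim = d)
  bx <- max(2L, floor(0.12 * nx)); by <- max(2L, floor(0.12 * ny))
  bz <- max(2L, floor(0.30 * nz))
  bg[seq_len(bx), seq_len(by), seq_len(bz)] <- TRUE
  bg <- bg & !kidney & !liver

  list(
    kidney = region_mask("kidney", kidney & !vessel),
    vessel = region_mask("vessel", vessel),
    liver = region_mask("liver", liver & !kidney),
    background = region_mask("background", bg)
  )
}

# Rasterize a main axial vessel plus four diagonal branches through the
# kidney centre, thickened to a 2-voxel-wide tube.
.vessel_tree <- function(d, centre, radii) {
  dirs <- rbind(
    c(0, 0, 1), c(0, 0, -1),
    c(0.8, 0.5, 0.5), c(-0.8, 0.5, -0.5),
    c(0.8, -0.5, -0.5), c(-0.8, -0.5, 0.5)
  )
  pts <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(r) {
    tt <- seq(0, 0.8, by = 0.02)
    cbind(
      centre[1] + tt * dirs[r, 1] * radii[1],
      centre[2] + tt * dirs[r, 2] * radii[2],
      centre[3] + tt * dirs[r, 3] * radii[3]
    )
  }))
  vox <- unique(round(pts))
  keep <- vox[, 1] >= 1 & vox[, 1] <= d[1] &
    vox[, 2] >= 1 & vox[, 2] <= d[2] &
    vox[, 3] >= 1 & vox[, 3] <= d[3]
  vox <- vox[keep, , drop = FALSE]
  out <- array(FALSE, dim = d)
  out[vox] <- TRUE
  # the tree stays thin (~1 voxel) so the bright-blood peak is a small mode
  # of the kidney histogram, as in a pre-contrast bright-blood acquisition
  out
}

# Acquisition noise applied to a clean signal array.
.apply_noise <- function(signal, model, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  if (model == "gaussian") {
    signal + stats::rnorm(n, 0, sigma)
  } else {
    # magnitude of (signal + e1) + i e2, the standard Rician MR noise model
    array(sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                 stats::rnorm(n, 0, sigma)^2), dim = dim(signal))
  }
}

# Clean (noise-free) tissue map plus masks; kidney texture is drawn here.
.tissue_map <- function(spec, masks) {
  d <- spec$geometry$matrix_size
  tissue <- array(0, dim = d)
  kid <- masks$kidney$voxels
  nk <- sum(kid)
  tissue[kid] <- spec$kidney_mean +
    if (spec$kidney_sd > 0) stats::rnorm(nk, 0, spec$kidney_sd) else 0
  tissue[masks$vessel$voxels] <- spec$vessel_intensity
  nl <- sum(masks$liver$voxels)
  tissue[masks$liver$voxels] <- spec$liver_mean +
    if (spec$kidney_sd > 0) stats::rnorm(nl, 0, spec$kidney_sd) else 0
  tissue
}

#' Generate a pre-contrast phantom volume
#'
#' Draws the baseline scene: Gaussian-textured kidney centred at
#' `kidney_mean` with spread `kidney_sd`, bright vessel tree, liver, and air
#' background, then applies the acquisition noise model. Bit-reproducible for
#' a fixed spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (an [image_volume()]) and `masks`
#'   (named list of disjoint [region_mask()]s: kidney parenchyma, vessel,
#'   liver, background).
#' @export
generate_precontrast <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  masks <- .organ_masks(spec$geometry)
  vol <- withr::with_seed(spec$seed, {
    tissue <- .tissue_map(spec, masks)
    .apply_noise(tissue, spec$noise_model, spec$noise_sigma)
  })
  list(volume = image_volume(vol, spec$geometry), masks = masks)
}

#' Generate a post-contrast phantom volume with ground truth
#'
#' Re-draws the scene with fresh texture and noise (a second acquisition),
#' paints exactly `spec$lesion_voxel_count` kidney voxels at
#' `lesion_intensity` arranged as `spec$n_clusters` contiguous clusters, and
#' copies the vessel voxels verbatim from the pre-contrast volume (flowing
#' blood is unaltered by bound contrast). The exact lesion voxel set is
#' returned as ground truth.
#'
#' @param pre Result of [generate_precontrast()] (list with `volume`,
#'   `masks`), or an [image_volume()] with the same geometry as `spec`.
#' @param spec The [phantom_spec()] used for the pre-contrast volume.
#' @param seed Seed for lesion placement and the fresh noise draw; defaults
#'   to `spec$seed + 1` so a pre/post pair is fully determined by the spec.
#' @return A list with elements `volume` (an [image_volume()]) and `truth`
#'   (a `phantom_truth` object: `lesion_voxels`, `vessel_voxels` as linear
#'   indices, `true_lesion_volume_um3`, `spec`, `seed`).
#' @export
generate_postcontrast <- function(pre, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  pre_vol <- if (inherits(pre, "image_volume")) pre else pre$volume
  if (!geometry_equal(pre_vol$geometry, spec$geometry)) {
    stop("pre-contrast volume geometry does not match the spec")
  }
  masks <- .organ_masks(spec$geometry)
  n_avail <- sum(masks$kidney$voxels)
  if (spec$lesion_voxel_count > n_avail) {
    stop(sprintf("lesion_voxel_count (%d) exceeds available kidney voxels (%d)",
                 spec$lesion_voxel_count, n_avail))
  }
  out <- withr::with_seed(as.integer(seed), {
    order_idx <- .lesion_accretion_order(
      masks$kidney$voxels, spec$lesion_voxel_count, spec$n_clusters
    )
    tissue <- .tissue_map(spec, masks)
    tissue[order_idx] <- spec$lesion_intensity
    noisy <- .apply_noise(tissue, spec$noise_model, spec$noise_sigma)
    list(data = noisy, lesions = order_idx)
  })
  data <- out$data
  vess <- masks$vessel$voxels
  data[vess] <- pre_vol$data[vess]
  truth <- structure(
    list(
      lesion_voxels = as.integer(sort(out$lesions)),
      vessel_voxels = which(vess),
      true_lesion_volume_um3 =
        length(out$lesions) * voxel_volume_um3(spec$geometry),
      spec = spec, seed = as.integer(seed)
    ),
    class = "phantom_truth"
  )
  list(volume = image_volume(data, spec$geometry), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom_truth: %d lesion voxels (%.4g um^3), %d vessel voxels, seed %d\n",
    length(x$lesion_voxels), x$true_lesion_volume_um3,
    length(x$vessel_voxels), x$seed
  ))
  invisible(x)
}

# Place n_total lesion voxels as n_clusters contiguous blobs inside `allowed`,
# grown by nearest-neighbour accretion in round-robin order. A voxel may not
# touch (26-neighbourhood) a different cluster, so the clusters are separate
# connected components by construction. Returns linear indices in accretion
# order; prefixes of the order are valid partially-grown lesion sets, which is
# what the serial generator relies on.
.lesion_accretion_order <- function(allowed, n_total, n_clusters) {
  if (n_total == 0L) return(integer(0))
  d <- dim(allowed)
  n_clusters <- min(n_clusters, n_total)
  allowed_idx <- which(allowed)

  per <- ceiling(n_total / n_clusters)
  min_sep <- 2 * ceiling((3 * per / (4 * pi))^(1 / 3)) + 3

  coords_of <- function(idx) arrayInd(idx, d)
  # seed voxels: rejection-sample for pairwise Chebyshev separation
  seeds <- integer(0)
  sep <- min_sep
  for (attempt in seq_len(200L)) {
    cand <- sample(allowed_idx, min(50L * n_clusters, length(allowed_idx)))
    seeds <- integer(0)
    sc <- matrix(numeric(0), ncol = 3)
    for (v in cand) {
      cv <- coords_of(v)
      if (nrow(sc) == 0 ||
          all(apply(abs(sweep(sc, 2, as.numeric(cv))), 1, max) >= sep)) {
        seeds <- c(seeds, v)
        sc <- rbind(sc, as.numeric(cv))
        if (length(seeds) == n_clusters) break
      }
    }
    if (length(seeds) == n_clusters) break
    sep <- max(3, sep - 1)  # relax if the region cannot host that separation
  }
  if (length(seeds) < n_clusters) {
    stop("could not place ", n_clusters, " separated lesion clusters")
  }

  nx <- d[1]; ny <- d[2]; nz <- d[3]
  off6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  off26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off26 <- off26[rowSums(abs(off26)) > 0, ]

  label <- array(0L, dim = d)
  queues <- vector("list", n_clusters)
  order_out <- integer(n_total)
  n_placed <- 0L

  lin <- function(c3) c3[1] + nx * (c3[2] - 1L) + nx * ny * (c3[3] - 1L)

  admissible <- function(cv, cl) {
    v <- lin(cv)
    if (!allowed[v] || label[v] != 0L) return(FALSE)
    nb <- sweep(off26, 2, cv, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny &
      nb[, 3] >= 1 & nb[, 3] <= nz
    nb <- nb[ok, , drop = FALSE]
    nl <- label[nb[, 1] + nx * (nb[, 2] - 1L) + nx * ny * (nb[, 3] - 1L)]
    !any(nl != 0L & nl != cl)
  }

  push_neighbours <- function(queues, cl, cv) {
    nb <- sweep(off6, 2, cv, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny &
      nb[, 3] >= 1 & nb[, 3] <= nz
    nb <- nb[ok, , drop = FALSE]
    queues[[cl]] <- c(queues[[cl]],
                      nb[, 1] + nx * (nb[, 2] - 1L) + nx * ny * (nb[, 3] - 1L))
    queues
  }

  for (cl in seq_len(n_clusters)) {
    cv <- as.integer(coords_of(seeds[cl]))
    if (!admissible(cv, cl)) stop("internal: seed voxel not admissible")
    label[seeds[cl]] <- cl
    n_placed <- n_placed + 1L
    order_out[n_placed] <- seeds[cl]
    queues <- push_neighbours(queues, cl, cv)
    if (n_placed == n_total) return(order_out[seq_len(n_placed)])
  }

  active <- rep(TRUE, n_clusters)
  while (n_placed < n_total && any(active)) {
    for (cl in which(active)) {
      if (n_placed == n_total) break
      placed <- FALSE
      while (length(queues[[cl]]) > 0L) {
        v <- queues[[cl]][1L]
        queues[[cl]] <- queues[[cl]][-1L]
        cv <- as.integer(coords_of(v))
        if (admissible(cv, cl)) {
          label[v] <- cl
          n_placed <- n_placed + 1L
          order_out[n_placed] <- v
          queues <- push_neighbours(queues, cl, cv)
          placed <- TRUE
          break
        }
      }
      if (!placed && length(queues[[cl]]) == 0L) active[cl] <- FALSE
    }
  }
  if (n_placed < n_total) {
    stop("lesion growth blocked before reaching the requested voxel count")
  }
  order_out
}

#' Generate a serial post-injection time series
#'
#' One volume per time point. The lesion voxel count at time `t` is
#' `round(lesion_voxel_count * bound_fraction(t))`, with the voxels taken as
#' a prefix of a single accretion order so lesion sets are nested and each
#' cluster grows in place. The liver mean decays exponentially toward
#' `liver_floor` with time constant `liver_decay_tau_min`, emulating
#' clearance of unbound particles.
#'
#' @param spec A [phantom_spec()]; `lesion_voxel_count` is the plateau count.
#' @param kin A [kinetics_spec()].
#' @return A list with one element per time point, each a list
#'   `(time_min, volume, truth)`, plus attribute `masks` (the shared organ
#'   masks).
#' @export
generate_serial_series <- function(spec, kin) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(kin, "kinetics_spec"))
  masks <- .organ_masks(spec$geometry)
  n_avail <- sum(masks$kidney$voxels)
  if (spec$lesion_voxel_count > n_avail) {
    stop("lesion_voxel_count exceeds available kidney voxels")
  }
  order_idx <- withr::with_seed(
    spec$seed + 104729L,
    .lesion_accretion_order(masks$kidney$voxels, spec$lesion_voxel_count,
                            spec$n_clusters)
  )
  vv3 <- voxel_volume_um3(spec$geometry)
  liv <- masks$liver$voxels
  out <- vector("list", length(kin$timepoints_min))
  for (i in seq_along(kin$timepoints_min)) {
    t <- kin$timepoints_min[i]
    n_t <- round(spec$lesion_voxel_count * bound_fraction(kin, t))
    lesions_t <- if (n_t > 0) order_idx[seq_len(n_t)] else integer(0)
    liver_mean_t <- kin$liver_floor +
      (spec$liver_mean - kin$liver_floor) * exp(-t / kin$liver_decay_tau_min)
    data <- withr::with_seed(spec$seed + 2000L + i, {
      tissue <- .tissue_map(spec, masks)
      shift <- liver_mean_t - spec$liver_mean
      tissue[liv] <- tissue[liv] + shift
      tissue[lesions_t] <- spec$lesion_intensity
      .apply_noise(tissue, spec$noise_model, spec$noise_sigma)
    })
    truth <- structure(
      list(
        lesion_voxels = as.integer(sort(lesions_t)),
        vessel_voxels = which(masks$vessel$voxels),
        true_lesion_volume_um3 = length(lesions_t) * vv3,
        spec = spec, seed = spec$seed + 2000L + i
      ),
      class = "phantom_truth"
    )
    out[[i]] <- list(time_min = t,
                     volume = image_volume(data, spec$geometry),
                     truth = truth)
  }
  attr(out, "masks") <- masks
  out
}

#' Generate paired volume--expression data
#'
#' For each ground truth, draws a relative mRNA expression linearly related
#' to the true lesion volume, `slope * volume + intercept + N(0, noise_sd)`,
#' floored at zero. This is the synthetic counterpart of paired per-kidney
#' contrast-volume and qPCR measurements used to exercise the regression
#' stage.
#'
#' @param truths List of `phantom_truth` objects (or a numeric vector of
#'   volumes in um^3).
#' @param slope Expression units per um^3.
#' @param intercept Expression at zero volume.
#' @param noise_sd SD of the additive Gaussian measurement noise (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `true_volume_um3`, `mrna_rel_expression`.
#' @export
generate_paired_expression <- function(truths, slope, intercept,
                                       noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  vols <- if (is.numeric(truths)) {
    as.numeric(truths)
  } else {
    vapply(truths, function(t) t$true_lesion_volume_um3, numeric(1))
  }
  if (length(unique(vols)) < 2L) {
    stop("need >= 2 distinct volumes for downstream regression")
  }
  expr <- withr::with_seed(as.integer(seed), {
    pmax(0, slope * vols + intercept + stats::rnorm(length(vols), 0, noise_sd))
  })
  data.frame(true_volume_um3 = vols, mrna_rel_expression = expr)
}

#' Write phantom ground truth as a JSON sidecar
#'
#' Records lesion and vessel voxel indices, the true volume, and the
#' generating parameters (including the seed) next to exported volumes.
#'
#' @param truth A `phantom_truth` object.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  obj <- list(
    lesion_voxels = truth$lesion_voxels,
    vessel_voxels = truth$vessel_voxels,
    true_lesion_volume_um3 = truth$true_lesion_volume_um3,
    seed = truth$seed,
    spec = list(
      fov_mm = spec$geometry$fov_mm, matrix_size = spec$geometry$matrix_size,
      kidney_mean = spec$kidney_mean, kidney_sd = spec$kidney_sd,
      vessel_intensity = spec$vessel_intensity,
      lesion_intensity = spec$lesion_intensity,
      lesion_voxel_count = spec$lesion_voxel_count,
      n_clusters = spec$n_clusters, noise_model = spec$noise_model,
      noise_sigma = spec$noise_sigma, liver_mean = spec$liver_mean,
      seed = spec$seed
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
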