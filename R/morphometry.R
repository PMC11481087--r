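#' Construct a multichannel voxel grid
#'
#' @param channels named list of 3D numeric arrays (`dim = c(nz, ny, nx)`)
#'   sharing one shape; conventional names are `nuclei`, `actin`,
#'   `marker`.
#' @param voxel_size voxel size `c(dx, dy, dz)`, um.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(channels, voxel_size) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  check_positive(voxel_size, "voxel_size")
  stopifnot(length(voxel_size) == 3)
  d <- dim(channels[[1]])
  for (ch in channels)
    if (!identical(dim(ch), d))
      stop("all channels must share one shape", call. = FALSE)
  structure(list(channels = channels, voxel_size = as.numeric(voxel_size)),
            class = "voxel_grid")
}

#' Gaussian-weighted median prefilter for the nuclei channel
#'
#' Replaces each voxel by the weighted median of its cubic neighbourhood,
#' the weights a Gaussian of `sigma` (voxels) centred on the voxel — the
#' despeckling prefilter applied to the DAPI channel before nuclei
#' segmentation. The output range never exceeds the input range.
#'
#' @param x a 3D array, or a [voxel_grid()] (then `channel` selects which).
#' @param radius neighbourhood Chebyshev radius, voxels (>= 1).
#' @param sigma Gaussian weight sigma, voxels.
#' @param channel channel name when `x` is a `voxel_grid`.
#' @return Filtered array of the same shape.
#' @export
prefilter_nuclei_channel <- function(x, radius = 1L, sigma = 1,
                                     channel = "nuclei") {
  if (inherits(x, "voxel_grid")) x <- x$channels[[channel]]
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  check_positive(sigma, "sigma")
  out <- cpp_weighted_median3d(as.numeric(as_slab(x)), arr_dims(x),
                               as.integer(radius), sigma)
  array(out, dim = dim(x))
}

#' Segment the whole spheroid from the cytoskeleton channel
#'
#' F-actin gating: smooth, global Otsu threshold, morphological closing,
#' hole filling, then keep the largest 26-connected component. Discarded
#' secondary components are reported in a warning.
#'
#' @param grid a [voxel_grid()] with an `actin` (or `channel`) channel.
#' @param channel channel used for gating.
#' @param smooth_sigma_um isotropic pre-smoothing sigma, um.
#' @param close_radius_um closing ball radius, um.
#' @return Logical spheroid mask (one 26-connected component).
#' @export
segment_spheroid <- function(grid, channel = "actin", smooth_sigma_um = 1,
                             close_radius_um = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(grid$channels[[channel]]))
    stop(sprintf("channel '%s' not present", channel), call. = FALSE)
  a <- grid$channels[[channel]]
  sm <- blur_physical(a, rep(smooth_sigma_um, 3), grid$voxel_size)
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  if (!any(fg)) stop("no spheroid detected", call. = FALSE)
  fg <- binary_closing(fg, close_radius_um, grid$voxel_size)
  fg <- fill_holes(fg)
  lab <- label_components(fg, 26L)
  n_comp <- max(lab)
  if (n_comp == 0L) stop("no spheroid detected", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
  keep <- which.max(sizes)
  if (n_comp > 1L)
    warning(sprintf("discarded %d smaller component(s) during gating",
                    n_comp - 1L))
  array(lab == keep, dim = dim(a))
}

# thin local-maxima candidates to a minimum pairwise physical separation,
# keeping the strongest first (deterministic tie-break by linear index)
thin_by_separation <- function(coords_um, values, min_sep_um) {
  ord <- order(-values, seq_along(values))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept)
      if (sqrt(sum((coords_um[i, ] - coords_um[j, ])^2)) < min_sep_um) {
        ok <- FALSE
        break
      }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

#' Segment nuclei by marker-controlled watershed
#'
#' Within the spheroid mask, the (prefiltered) nuclei channel is Otsu
#' thresholded; markers are local maxima of the smoothed anisotropic
#' Euclidean distance transform, kept only above a fraction `h_frac` of
#' the distance maximum and thinned to a minimum physical separation
#' (about one nuclear radius); a marker-controlled watershed on the
#' inverted distance map splits touching nuclei, and labels below the
#' minimum nucleus volume are removed.
#'
#' @param nuclei filtered nuclei-channel array (see
#'   [prefilter_nuclei_channel()]).
#' @param spheroid_mask logical mask from [segment_spheroid()].
#' @param voxel_size voxel size `c(dx, dy, dz)`, um.
#' @param h_frac marker height floor as a fraction of the distance-map
#'   maximum.
#' @param min_sep_um minimum marker separation, um (about one nuclear
#'   radius).
#' @param min_volume_um3 minimum nucleus volume, um^3; smaller labels are
#'   debris and removed.
#' @param smooth_sigma_um Gaussian sigma for distance-map smoothing, um.
#' @return Integer label array (0 = background), labels 1..K inside the
#'   spheroid mask.
#' @export
segment_nuclei <- function(nuclei, spheroid_mask, voxel_size,
                           h_frac = 0.3, min_sep_um = 4,
                           min_volume_um3 = 50, smooth_sigma_um = 0.5) {
  stopifnot(all(dim(nuclei) == dim(spheroid_mask)))
  if (!any(spheroid_mask)) stop("spheroid mask is empty", call. = FALSE)
  vals <- nuclei[spheroid_mask]
  thr <- otsu_threshold(vals)
  fg <- nuclei > thr & spheroid_mask
  if (!any(fg)) stop("no nuclei detected", call. = FALSE)

  dist <- distance_transform(fg, voxel_size)
  dsm <- blur_physical(dist, rep(smooth_sigma_um, 3), voxel_size)
  dsm[!fg] <- 0
  peaks <- cpp_local_maxima(as.numeric(as_slab(dsm)), arr_dims(dsm),
                            as.integer(as_slab(fg)),
                            h_frac * max(dsm))
  idx <- which(array(peaks, dim = dim(fg)))
  if (!length(idx)) stop("no nuclei detected", call. = FALSE)
  d <- dim(fg)
  co <- arrayInd(idx, d)
  sp <- spacing_zyx(voxel_size)
  coords_um <- sweep(co, 2, sp, `*`)
  kept <- thin_by_separation(coords_um, dsm[idx], min_sep_um)

  markers <- array(0L, dim = d)
  markers[idx[kept]] <- seq_along(kept)
  lab <- cpp_watershed(as.numeric(as_slab(dsm)),
                       as.integer(as_slab(markers)),
                       as.integer(as_slab(fg)), arr_dims(fg))
  lab <- array(lab, dim = d)

  voxvol <- prod(voxel_size)
  n0 <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = n0)
  small <- which(sizes * voxvol < min_volume_um3)
  if (length(small)) lab[lab %in% small] <- 0L
  remap <- integer(n0)
  keep_ids <- sort(setdiff(unique(lab[lab > 0L]), 0L))
  if (!length(keep_ids)) stop("no nuclei detected", call. = FALSE)
  remap[keep_ids] <- seq_along(keep_ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Compartmental volume statistics of a segmented spheroid
#'
#' Voxel-based volumes: each compartment volume is its voxel count times
#' the physical voxel volume; cytoplasmic volume is spheroid minus
#' nuclear; per-cell volume is spheroid volume divided by nuclei count
#' (the 3D proxy for individual cell volume).
#'
#' @param spheroid_mask logical spheroid mask.
#' @param nuclei_labels integer nuclei label array.
#' @param voxel_size voxel size `c(dx, dy, dz)`, um.
#' @param position_mm optional gradient position tag, mm.
#' @param stiffness_kPa optional local stiffness tag, kPa.
#' @param spheroid_id optional identifier.
#' @return A one-row data frame of class `morphometry_record` with columns
#'   `spheroid_id`, `position_mm`, `stiffness_kPa`, `spheroid_volume_um3`,
#'   `nuclear_volume_um3`, `cytoplasmic_volume_um3`, `nuclei_count`,
#'   `cell_volume_um3`.
#' @export
compute_morphometry <- function(spheroid_mask, nuclei_labels, voxel_size,
                                position_mm = NA_real_,
                                stiffness_kPa = NA_real_,
                                spheroid_id = "spheroid_1") {
  stopifnot(all(dim(spheroid_mask) == dim(nuclei_labels)))
  voxvol <- prod(voxel_size)
  n_nuclei <- length(setdiff(unique(as.integer(nuclei_labels)), 0L))
  if (n_nuclei == 0L)
    stop("cell volume undefined: no nuclei in segmentation", call. = FALSE)
  if (any(nuclei_labels > 0L & !spheroid_mask))
    warning("nuclei labels extend outside the spheroid mask")
  vs <- sum(spheroid_mask) * voxvol
  vn <- sum(nuclei_labels > 0L & spheroid_mask) * voxvol
  out <- data.frame(spheroid_id = spheroid_id,
                    position_mm = position_mm,
                    stiffness_kPa = stiffness_kPa,
                    spheroid_volume_um3 = vs,
                    nuclear_volume_um3 = vn,
                    cytoplasmic_volume_um3 = vs - vn,
                    nuclei_count = n_nuclei,
                    cell_volume_um3 = vs / n_nuclei)
  class(out) <- c("morphometry_record", "data.frame")
  out
}

#' Central maximum-intensity projection
#'
#' Maximum-intensity projection over an axial window of the given
#' physical thickness centred on the spheroid's axial centroid — the
#' display convention for mid-spheroid projections.
#'
#' @param grid a [voxel_grid()].
#' @param thickness_um axial window thickness, um.
#' @param spheroid_mask logical mask locating the spheroid.
#' @return Named list of 2D matrices, one per channel.
#' @export
central_mip <- function(grid, thickness_um, spheroid_mask) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$channels[[1]])
  dz <- grid$voxel_size[3]
  zc <- round(mean(which(apply(spheroid_mask, 1, any))))
  halfn <- round(thickness_um / dz / 2)
  z0 <- zc - halfn
  z1 <- zc + halfn
  if (z0 < 1 || z1 > d[1]) {
    warning(sprintf(
      "projection window (%g um) clipped to the %g um stack depth",
      thickness_um, d[1] * dz))
    z0 <- max(1L, z0)
    z1 <- min(d[1], z1)
  }
  lapply(grid$channels, function(ch)
    apply(ch[z0:z1, , , drop = FALSE], c(2, 3), max))
}

#' Projected areas of a 2D time-lapse
#'
#' Per frame: Otsu threshold, keep the largest 8-connected component,
#' report its area in um^2. Empty frames yield 0 with a warning.
#'
#' @param frames list of 2D matrices (one per time point).
#' @param pixel_size_um lateral pixel size, um (square pixels).
#' @return Numeric vector of areas, um^2.
#' @export
projected_area <- function(frames, pixel_size_um = 1) {
  stopifnot(is.list(frames))
  check_positive(pixel_size_um, "pixel_size_um")
  vapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    if (diff(range(fr)) == 0) {
      warning(sprintf("frame %d is empty; area 0", i))
      return(0)
    }
    thr <- otsu_threshold(fr)
    fg <- fr > thr
    if (!any(fg)) {
      warning(sprintf("frame %d is empty; area 0", i))
      return(0)
    }
    lab <- label_components(as_slab(fg), 26L)
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    max(sizes) * pixel_size_um^2
  }, numeric(1))
}
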