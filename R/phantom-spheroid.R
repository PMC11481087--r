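#' Configuration for a synthetic spheroid z-stack
#'
#' Describes a fluorescence z-stack phantom of one spheroid: `n_nuclei`
#' ellipsoidal nuclei of constant volume packed without overlap inside a
#' spherical envelope whose target volume is `n_nuclei * cell_volume`,
#' imaged into three channels (`nuclei`, `actin`, `marker`) with Gaussian
#' optical blur, Poisson shot noise and additive Gaussian read noise.
#'
#' The marker channel is scaled so that its mean over the spheroid equals
#' `marker_law$amplitude * exp(marker_law$rate * V)` at the voxel-counted
#' spheroid volume `V`, with the nuclear-to-cytoplasmic intensity ratio
#' fixed at `yap_ratio_true` (the ground truth for YAP-style readouts).
#'
#' Defaults describe a desk-scale spheroid: eight cells of 2000 um^3 with
#' 250 um^3 nuclei, sampled at 0.3 x 0.3 um laterally and 0.5 um axially
#' (the axial step used for confocal acquisition of gradient-grown
#' spheroids).
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param nuclear_volume per-nucleus volume, um^3 (constant across cells).
#' @param cell_volume per-cell volume, um^3; the spheroid envelope targets
#'   `n_nuclei * cell_volume`.
#' @param voxel_size voxel size `c(dx, dy, dz)` in um.
#' @param stack_shape stack dimensions `c(nz, ny, nx)` in voxels, or `NULL`
#'   to auto-size with a margin.
#' @param blur_sigma isotropic Gaussian PSF proxy sigma, um.
#' @param noise list with `gaussian_sd` (additive read noise, intensity
#'   units) and `poisson_scale` (photons per intensity unit; 0 disables
#'   shot noise).
#' @param marker_law list with `amplitude` and `rate` of the exponential
#'   intensity-volume law `I = a * exp(b * V)`.
#' @param yap_ratio_true true nuclear/cytoplasmic marker intensity ratio.
#' @param touching_pairs logical; place nuclei in touching pairs to
#'   exercise watershed splitting.
#' @param seed integer RNG seed.
#' @return An object of class `spheroid_phantom_config`.
#' @seealso [generate_spheroid_stack()]
#' @export
spheroid_phantom_config <- function(n_nuclei = 8,
                                    nuclear_volume = 250,
                                    cell_volume = 2000,
                                    voxel_size = c(0.3, 0.3, 0.5),
                                    stack_shape = NULL,
                                    blur_sigma = 0.5,
                                    noise = list(gaussian_sd = 0,
                                                 poisson_scale = 0),
                                    marker_law = list(amplitude = 2,
                                                      rate = 1e-4),
                                    yap_ratio_true = 0.8,
                                    touching_pairs = FALSE,
                                    seed = 1L) {
  stopifnot(n_nuclei >= 1, length(voxel_size) == 3L)
  check_positive(nuclear_volume, "nuclear_volume")
  check_positive(cell_volume, "cell_volume")
  check_positive(voxel_size, "voxel_size")
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)
  if (nuclear_volume > cell_volume)
    stop("nuclear_volume exceeds cell_volume: nuclei cannot pack",
         call. = FALSE)
  cfg <- list(n_nuclei = as.integer(n_nuclei),
              nuclear_volume = nuclear_volume,
              cell_volume = cell_volume,
              voxel_size = as.numeric(voxel_size),
              stack_shape = if (!is.null(stack_shape)) as.integer(stack_shape),
              blur_sigma = blur_sigma,
              noise = list(gaussian_sd = noise$gaussian_sd %||% 0,
                           poisson_scale = noise$poisson_scale %||% 0),
              marker_law = list(amplitude = marker_law$amplitude %||% 2,
                                rate = marker_law$rate %||% 1e-4),
              yap_ratio_true = yap_ratio_true,
              touching_pairs = isTRUE(touching_pairs),
              seed = as.integer(seed))
  class(cfg) <- "spheroid_phantom_config"
  cfg
}

# effective radius of an axis-aligned ellipsoid along a unit direction
ellipsoid_radius_along <- function(semi, dir) {
  1 / sqrt(sum((dir / semi)^2))
}

#' Generate a synthetic multichannel spheroid z-stack with ground truth
#'
#' Packs non-overlapping ellipsoidal nuclei into a spherical envelope by
#' seeded rejection sampling, voxelizes the three channels, then applies
#' optical blur and noise per the configuration. The truth record reports
#' voxel-counted (not nominal) volumes, so it is exactly recomputable by
#' brute-force voxel counting on the noiseless masks.
#'
#' @param config a [spheroid_phantom_config()].
#' @return A list of class `spheroid_phantom` with elements
#'   * `stack`: named list of 3D arrays (`nuclei`, `actin`, `marker`),
#'     each `dim = c(nz, ny, nx)`;
#'   * `truth`: class `phantom_truth` — voxel-counted `spheroid_volume`
#'     and `nuclear_volume_total` (um^3), `nuclei_centroids` (matrix of
#'     placement centres, um, columns z/y/x), `nuclei_count`,
#'     `marker_mean_intensity`, `yap_ratio`, `seed`, plus the noiseless
#'     `spheroid_mask` and `nuclei_labels` arrays;
#'   * `config`: the input configuration.
#' @export
generate_spheroid_stack <- function(config) {
  stopifnot(inherits(config, "spheroid_phantom_config"))
  cfg <- config
  sp <- spacing_zyx(cfg$voxel_size)            # (dz, dy, dx)
  voxvol <- prod(cfg$voxel_size)
  V_target <- cfg$n_nuclei * cfg$cell_volume
  R <- (3 * V_target / (4 * pi))^(1 / 3)
  r_n <- (3 * cfg$nuclear_volume / (4 * pi))^(1 / 3)

  margin <- cfg$blur_sigma + max(sp)           # >= blur_sigma by invariant
  dims <- cfg$stack_shape %||%
    as.integer(ceiling(2 * (R + margin + max(sp)) / sp))
  ext <- dims * sp
  axis_names <- c("z", "y", "x")
  short <- which(ext / 2 < R + cfg$blur_sigma)
  if (length(short))
    stop(sprintf(
      "spheroid of radius %.1f um (+%.1f um blur margin) does not fit: %s",
      R, cfg$blur_sigma,
      paste0(axis_names[short], " extent ", signif(ext[short], 4), " um",
             collapse = ", ")), call. = FALSE)
  ctr <- ext / 2

  with_seed(cfg$seed, {
    # nuclei geometry: axis-aligned ellipsoids of exactly nuclear_volume
    semis <- matrix(0, cfg$n_nuclei, 3)
    for (i in seq_len(cfg$n_nuclei)) {
      f <- runif(2, 0.9, 1.12)
      semis[i, ] <- r_n * c(f[1], f[2], 1 / prod(f))
    }
    max_semi <- apply(semis, 1, max)
    # cortical cytoplasm: nuclei never touch the spheroid surface, so the
    # F-actin shell used for gating is at least this thick
    cortex <- min(1.5, 0.15 * R)
    if (any(R - max_semi - cortex <= 0))
      stop("nuclei are larger than the spheroid envelope", call. = FALSE)

    # rejection sampling with direction-aware ellipsoid separation; a
    # stuck configuration restarts from scratch (still fully seeded)
    centers <- matrix(NA_real_, cfg$n_nuclei, 3)
    placed <- 0L
    restarts <- 0L
    stuck <- 0L
    while (placed < cfg$n_nuclei && restarts <= 20L) {
      if (stuck > 1500L) {
        placed <- 0L
        stuck <- 0L
        restarts <- restarts + 1L
        next
      }
      i <- placed + 1L
      pair_with <- if (cfg$touching_pairs && i %% 2L == 0L) i - 1L else 0L
      if (pair_with > 0L) {
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        gap <- 0.95 * (ellipsoid_radius_along(semis[pair_with, ], dir) +
                         ellipsoid_radius_along(semis[i, ], dir))
        cand <- centers[pair_with, ] + dir * gap
        if (sqrt(sum((cand - ctr)^2)) > R - max_semi[i] - cortex) {
          stuck <- stuck + 1L
          next
        }
      } else {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        rad <- (R - max_semi[i] - cortex) * runif(1)^(1 / 3)
        cand <- ctr + u * rad
      }
      ok <- TRUE
      for (j in seq_len(placed)) {
        if (j == pair_with) next
        dvec <- cand - centers[j, ]
        dist <- sqrt(sum(dvec^2))
        dir_j <- dvec / max(dist, 1e-12)
        # well-separated in normal mode; barely clearing in pairs mode so
        # only the deliberate pairs touch
        sep_factor <- if (cfg$touching_pairs) 1.02 else 1.15
        need <- sep_factor * (ellipsoid_radius_along(semis[i, ], dir_j) +
                                ellipsoid_radius_along(semis[j, ], dir_j))
        if (dist < need) { ok <- FALSE; break }
      }
      if (ok) {
        centers[i, ] <- cand
        placed <- i
        stuck <- 0L
      } else stuck <- stuck + 1L
    }
    if (placed < cfg$n_nuclei)
      stop(sprintf(
        "could not pack %d nuclei of %.0f um^3 into a %.0f um^3 envelope",
        cfg$n_nuclei, cfg$nuclear_volume, V_target), call. = FALSE)

    # voxelization on voxel centres
    zc <- (seq_len(dims[1]) - 0.5) * sp[1]
    yc <- (seq_len(dims[2]) - 0.5) * sp[2]
    xc <- (seq_len(dims[3]) - 0.5) * sp[3]
    d2 <- outer(outer((zc - ctr[1])^2, (yc - ctr[2])^2, "+"),
                (xc - ctr[3])^2, "+")
    env <- d2 <= R^2

    labels <- array(0L, dim = dims)
    for (i in seq_len(cfg$n_nuclei)) {
      cen <- centers[i, ]
      se <- semis[i, ]
      zi <- which(abs(zc - cen[1]) <= se[1])
      yi <- which(abs(yc - cen[2]) <= se[2])
      xi <- which(abs(xc - cen[3]) <= se[3])
      if (!length(zi) || !length(yi) || !length(xi)) next
      q <- outer(outer(((zc[zi] - cen[1]) / se[1])^2,
                       ((yc[yi] - cen[2]) / se[2])^2, "+"),
                 ((xc[xi] - cen[3]) / se[3])^2, "+")
      sub <- labels[zi, yi, xi, drop = FALSE]
      sub[q <= 1] <- i
      labels[zi, yi, xi] <- sub
    }
    nuc_mask <- labels > 0L

    spheroid_volume <- sum(env) * voxvol
    nuclear_volume_total <- sum(nuc_mask) * voxvol

    marker_mean <- cfg$marker_law$amplitude *
      exp(cfg$marker_law$rate * spheroid_volume)
    fn <- sum(nuc_mask & env) / sum(env)
    cyt_int <- marker_mean / (1 - fn + cfg$yap_ratio_true * fn)

    ch_nuclei <- array(as.numeric(nuc_mask), dim = dims)
    ch_actin <- array(as.numeric(env & !nuc_mask), dim = dims)
    ch_marker <- array(0, dim = dims)
    ch_marker[env] <- cyt_int
    ch_marker[nuc_mask & env] <- cyt_int * cfg$yap_ratio_true

    degrade <- function(a) {
      if (cfg$blur_sigma > 0)
        a <- blur_physical(a, rep(cfg$blur_sigma, 3), cfg$voxel_size)
      if (cfg$noise$poisson_scale > 0)
        a <- array(rpois(length(a), pmax(a, 0) * cfg$noise$poisson_scale) /
                     cfg$noise$poisson_scale, dim = dim(a))
      if (cfg$noise$gaussian_sd > 0)
        a <- a + array(rnorm(length(a), 0, cfg$noise$gaussian_sd),
                       dim = dim(a))
      a
    }

    truth <- structure(list(
      spheroid_volume = spheroid_volume,
      nuclear_volume_total = nuclear_volume_total,
      nuclei_centroids = centers,
      nuclei_count = cfg$n_nuclei,
      marker_mean_intensity = marker_mean,
      yap_ratio = cfg$yap_ratio_true,
      spheroid_mask = env,
      nuclei_labels = labels,
      seed = cfg$seed), class = "phantom_truth")

    structure(list(
      stack = list(nuclei = degrade(ch_nuclei),
                   actin = degrade(ch_actin),
                   marker = degrade(ch_marker)),
      truth = truth,
      config = cfg), class = "spheroid_phantom")
  })
}

#' @export
print.spheroid_phantom <- function(x, ...) {
  d <- dim(x$stack$nuclei)
  cat(sprintf(
    "spheroid phantom: %d x %d x %d voxels (z,y,x), %d nuclei\n",
    d[1], d[2], d[3], x$truth$nuclei_count))
  cat(sprintf("  spheroid volume %.0f um^3, nuclear total %.0f um^3\n",
              x$truth$spheroid_volume, x$truth$nuclear_volume_total))
  invisible(x)
}
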