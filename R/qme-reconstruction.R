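#' OCT acquisition metadata
#'
#' @param wavelength_nm central wavelength, nm (default 1300).
#' @param refractive_index assumed sample refractive index (default 1.4).
#' @param pixel_size `c(axial, lateral)` pixel size, um.
#' @param snr optional per-pixel linear SNR matrix (same dims as the
#'   phase field) used for validity gating and WLS weights.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(wavelength_nm = 1300, refractive_index = 1.4,
                             pixel_size = c(axial = 2.4, lateral = 2.2),
                             snr = NULL) {
  check_positive(wavelength_nm, "wavelength_nm")
  check_positive(refractive_index, "refractive_index")
  check_positive(pixel_size, "pixel_size")
  structure(list(wavelength_nm = wavelength_nm,
                 refractive_index = refractive_index,
                 pixel_size = as.numeric(pixel_size),
                 snr = snr),
            class = "acquisition_meta")
}

#' Lateral pixel size from scan geometry
#'
#' A B-scan spanning `scan_width_mm` sampled with `n_ascans` A-scans has a
#' lateral pixel of `scan_width_mm * 1000 / n_ascans` micrometres (e.g. a
#' 2.2 mm scan at 1000 A-scans per B-scan gives 2.2 um).
#'
#' @param scan_width_mm lateral scan width, mm.
#' @param n_ascans A-scans per B-scan.
#' @return Lateral pixel size, um.
#' @export
lateral_pixel_size <- function(scan_width_mm = 2.2, n_ascans = 1000) {
  check_positive(scan_width_mm, "scan_width_mm")
  check_positive(n_ascans, "n_ascans")
  scan_width_mm * 1000 / n_ascans
}

#' Axial displacement from a wrapped phase-difference field
#'
#' Unwraps each A-line (column) axially by nearest-2-pi correction of
#' successive increments, then converts phase to displacement with the
#' double-pass relation `u_z = lambda0 * phi / (4 pi n)`. Pixels whose
#' phase increment sits at the aliasing bound, or whose SNR falls below
#' `snr_floor` when an SNR map is supplied, are flagged invalid.
#'
#' @param phase wrapped phase-difference matrix `c(nz, nx)`, radians in
#'   (-pi, pi].
#' @param meta an [acquisition_meta()].
#' @param snr_floor linear SNR validity floor (used only with `meta$snr`).
#' @return A list of class `displacement_field` with `u_z` (um) and
#'   logical `validity`.
#' @export
displacement_from_phase <- function(phase, meta, snr_floor = 2) {
  stopifnot(is.matrix(phase), inherits(meta, "acquisition_meta"))
  if (max(abs(phase)) > pi + 1e-9)
    stop("phase must be wrapped to (-pi, pi]", call. = FALSE)
  nz <- nrow(phase)
  inc <- wrap_phase(phase[-1, , drop = FALSE] - phase[-nz, , drop = FALSE])
  unwrapped <- apply(rbind(phase[1, ], inc), 2, cumsum)
  if (nz == 1L) unwrapped <- matrix(unwrapped, nrow = 1L)
  lambda_um <- meta$wavelength_nm / 1000
  u <- lambda_um * unwrapped / (4 * pi * meta$refractive_index)
  validity <- matrix(TRUE, nz, ncol(phase))
  # increments at the +-pi bound are ambiguous: flag both pixels involved
  at_bound <- abs(abs(inc) - pi) < 1e-6
  if (any(at_bound)) {
    validity[-1, ][at_bound] <- FALSE
    validity[-nz, ][at_bound] <- FALSE
  }
  if (!is.null(meta$snr)) validity <- validity & (meta$snr >= snr_floor)
  structure(list(u_z = u, validity = validity),
            class = "displacement_field")
}

#' Local axial strain by weighted-least-squares regression
#'
#' At each pixel the axial displacement is regressed on depth over a
#' centred axial window by weighted least squares (weights `snr^2` when an
#' SNR map is present, uniform otherwise); the slope is the local strain.
#' The strain field is then spatially averaged with a Gaussian kernel so
#' that the effective (FWHM) resolution reaches `resolution_um`
#' isotropically, mirroring the ~35 um strain resolution of the
#' instrument this emulates. Edge pixels whose window leaves the data are
#' flagged invalid.
#'
#' @param disp a [displacement_from_phase()] result.
#' @param meta an [acquisition_meta()].
#' @param fit_window_um axial regression window, um (>= 3 axial pixels).
#' @param resolution_um target isotropic strain resolution (FWHM), um;
#'   `NULL` or <= `fit_window_um` disables the extra smoothing.
#' @param weights optional explicit weight matrix overriding the SNR rule.
#' @return A list of class `strain_field` with `strain`, logical
#'   `validity` and `resolution_um`.
#' @export
strain_wls <- function(disp, meta, fit_window_um = 25,
                       resolution_um = 35, weights = NULL) {
  stopifnot(inherits(disp, "displacement_field"),
            inherits(meta, "acquisition_meta"))
  u <- disp$u_z
  nz <- nrow(u)
  nx <- ncol(u)
  dz <- meta$pixel_size[1]
  half <- max(1L, round((fit_window_um / dz - 1) / 2))
  if (2L * half + 1L > nz)
    stop("fit window exceeds the axial extent of the data", call. = FALSE)
  w <- weights %||%
    (if (!is.null(meta$snr)) meta$snr^2 else matrix(1, nz, nx))
  w[!disp$validity] <- 0

  Sw <- Swd <- Swdd <- Swu <- Swdu <- matrix(0, nz, nx)
  for (o in -half:half) {
    rows_to <- max(1, 1 - o):min(nz, nz - o)
    rows_from <- rows_to + o
    d <- o * dz
    wo <- w[rows_from, , drop = FALSE]
    uo <- u[rows_from, , drop = FALSE]
    Sw[rows_to, ] <- Sw[rows_to, ] + wo
    Swd[rows_to, ] <- Swd[rows_to, ] + wo * d
    Swdd[rows_to, ] <- Swdd[rows_to, ] + wo * d^2
    Swu[rows_to, ] <- Swu[rows_to, ] + wo * uo
    Swdu[rows_to, ] <- Swdu[rows_to, ] + wo * uo * d
  }
  denom <- Sw * Swdd - Swd^2
  strain <- (Sw * Swdu - Swd * Swu) / denom
  strain[!is.finite(strain)] <- NA_real_

  validity <- disp$validity
  validity[c(seq_len(half), nz - seq_len(half) + 1L), ] <- FALSE
  validity <- validity & is.finite(strain)

  res <- fit_window_um
  if (!is.null(resolution_um)) {
    dx <- meta$pixel_size[2]
    sig_lat <- resolution_um / 2.3548 / dx
    extra_ax <- sqrt(max(0, resolution_um^2 - fit_window_um^2))
    sig_ax <- extra_ax / 2.3548 / dz
    # normalised masked convolution keeps invalid pixels out of the average
    sm <- function(a, sz, sx) {
      array(cpp_gaussian_blur3d(as.numeric(as_slab(a)),
                                arr_dims(a), c(0, sz, sx)),
            dim = dim(as_slab(a)))[1, , ]
    }
    vnum <- strain
    vnum[!validity] <- 0
    vden <- matrix(as.numeric(validity), nz, nx)
    num <- sm(vnum, sig_ax, sig_lat)
    den <- sm(vden, sig_ax, sig_lat)
    strain <- ifelse(den > 1e-8, num / den, NA_real_)
    res <- max(resolution_um, fit_window_um)
  }
  strain[!validity] <- NA_real_
  structure(list(strain = strain, validity = validity,
                 resolution_um = res),
            class = "strain_field")
}

#' Compliant-layer stress-strain calibration
#'
#' Tabulated uniaxial stress-strain behaviour of the compliant silicone
#' layer, with the preload operating point and the axial pixel band the
#' layer occupies in the B-scan.
#'
#' @param strain tabulated strain values (non-negative, increasing).
#' @param stress_kPa tabulated stress, kPa, monotone non-decreasing.
#' @param preload_strain preload strain fraction (~0.05).
#' @param layer_band `c(first, last)` axial pixel rows of the layer.
#' @return An object of class `layer_calibration`.
#' @export
layer_calibration <- function(strain, stress_kPa, preload_strain = 0.05,
                              layer_band) {
  stopifnot(length(strain) == length(stress_kPa), length(strain) >= 2)
  if (any(diff(strain) <= 0))
    stop("calibration strains must be strictly increasing", call. = FALSE)
  if (any(diff(stress_kPa) < 0))
    stop("calibration stress must be monotone non-decreasing", call. = FALSE)
  if (preload_strain < 0 || preload_strain >= 1)
    stop("`preload_strain` must be in [0, 1)", call. = FALSE)
  stopifnot(length(layer_band) == 2, layer_band[1] >= 1,
            layer_band[2] >= layer_band[1])
  structure(list(strain = as.numeric(strain),
                 stress_kPa = as.numeric(stress_kPa),
                 preload_strain = preload_strain,
                 layer_band = as.integer(layer_band)),
            class = "layer_calibration")
}

#' Linear compliant-layer calibration helper
#'
#' Convenience constructor for a linear stress-strain curve
#' `sigma = E_layer * strain`, tabulated densely over `[0, strain_max]`.
#'
#' @param E_layer_kPa layer Young's modulus, kPa.
#' @param layer_band `c(first, last)` axial pixel rows of the layer.
#' @param preload_strain preload strain fraction.
#' @param strain_max upper end of the tabulated range.
#' @return A [layer_calibration()].
#' @export
linear_layer_calibration <- function(E_layer_kPa, layer_band,
                                     preload_strain = 0, strain_max = 0.2) {
  s <- seq(0, strain_max, length.out = 201)
  layer_calibration(s, E_layer_kPa * s, preload_strain, layer_band)
}

# interpolate the tabulated curve; refuse extrapolation
eval_layer_curve <- function(cal, strain, what = "strain") {
  rng <- range(cal$strain)
  bad <- strain < rng[1] - 1e-12 | strain > rng[2] + 1e-12
  if (any(bad))
    stop(sprintf(
      "layer strain %s outside the calibrated range [%g, %g] at %s %s",
      paste(signif(strain[bad], 4), collapse = ", "), rng[1], rng[2],
      what, paste(which(bad), collapse = ", ")), call. = FALSE)
  approx(cal$strain, cal$stress_kPa, xout = strain, rule = 1)$y
}

#' Local axial stress at the layer-sample interface
#'
#' Per lateral position, the mean (valid) strain inside the compliant
#' layer band, offset by the preload strain, is pushed through the
#' layer's stress-strain curve; the stress increment relative to the
#' preload operating point is the local axial stress transmitted to the
#' sample. With a zero preload this reduces to evaluating the curve at
#' the measured layer strain.
#'
#' @param strain a [strain_wls()] result.
#' @param cal a [layer_calibration()].
#' @return A list of class `stress_map` with `stress_kPa` (one value per
#'   lateral position) and `layer_strain`.
#' @export
layer_stress <- function(strain, cal) {
  stopifnot(inherits(strain, "strain_field"),
            inherits(cal, "layer_calibration"))
  band <- seq(cal$layer_band[1], min(cal$layer_band[2], nrow(strain$strain)))
  eps_l <- vapply(seq_len(ncol(strain$strain)), function(j) {
    v <- strain$strain[band, j][strain$validity[band, j]]
    if (!length(v)) return(NA_real_)
    mean(v)
  }, numeric(1))
  total <- eps_l + cal$preload_strain
  sigma0 <- eval_layer_curve(cal, cal$preload_strain, "preload")
  sig <- eval_layer_curve(cal, total[!is.na(total)], "lateral position")
  stress <- rep(NA_real_, length(total))
  stress[!is.na(total)] <- sig - sigma0
  structure(list(stress_kPa = stress, layer_strain = eps_l),
            class = "stress_map")
}

#' Assemble the elastogram (tangent modulus map)
#'
#' Under the uniaxial-stress assumption the local elasticity is the
#' tangent modulus `E(x, z) = sigma(x) / strain(x, z)` at the preload
#' operating point. Pixels with strain magnitude below `strain_floor`, or
#' invalid strain/stress, are excluded from the validity mask.
#'
#' @param strain a [strain_wls()] result.
#' @param stress a [layer_stress()] result.
#' @param strain_floor strain magnitude validity floor.
#' @param display_range display range in kPa (0 blue to 20 red by
#'   convention).
#' @return An object of class `elastogram` with `E` (kPa), `stress_kPa`,
#'   `validity` and `display_range`.
#' @export
build_elastogram <- function(strain, stress, strain_floor = 1e-5,
                             display_range = c(0, 20)) {
  stopifnot(inherits(strain, "strain_field"),
            inherits(stress, "stress_map"))
  eps <- strain$strain
  sig <- matrix(stress$stress_kPa, nrow(eps), ncol(eps), byrow = TRUE)
  E <- sig / eps
  validity <- strain$validity & is.finite(E) & !is.na(sig) &
    abs(eps) > strain_floor
  E[!validity] <- NA_real_
  structure(list(E = E, stress_kPa = stress$stress_kPa,
                 validity = validity,
                 display_range = as.numeric(display_range)),
            class = "elastogram")
}

#' Reconstruct an elastogram from wrapped phase data in one call
#'
#' Chains [displacement_from_phase()], [strain_wls()], [layer_stress()]
#' and [build_elastogram()].
#'
#' @param phase wrapped phase-difference matrix.
#' @param meta an [acquisition_meta()].
#' @param cal a [layer_calibration()].
#' @param fit_window_um axial regression window, um.
#' @param resolution_um target strain resolution, um.
#' @param strain_floor strain validity floor.
#' @return An `elastogram`.
#' @export
reconstruct_elastogram <- function(phase, meta, cal, fit_window_um = 25,
                                   resolution_um = 35, strain_floor = 1e-5) {
  disp <- displacement_from_phase(phase, meta)
  eps <- strain_wls(disp, meta, fit_window_um = fit_window_um,
                    resolution_um = resolution_um)
  sig <- layer_stress(eps, cal)
  build_elastogram(eps, sig, strain_floor = strain_floor)
}

#' Histogram peaks of an elastogram
#'
#' Summarises the elasticity distribution of each region by the mode of a
#' Gaussian kernel-density estimate (Silverman bandwidth) over valid
#' pixels. With a spheroid mask, `background` is the region outside the
#' mask and `spheroid` inside; without one, a single `background` peak is
#' returned.
#'
#' @param elast an [build_elastogram()] result.
#' @param spheroid_mask optional logical matrix marking the spheroid.
#' @param min_pixels minimum valid pixels per region (default 100).
#' @return A list with `background_peak_kPa` and (with a mask)
#'   `spheroid_peak_kPa`.
#' @export
histogram_peaks <- function(elast, spheroid_mask = NULL, min_pixels = 100) {
  stopifnot(inherits(elast, "elastogram"))
  kde_mode <- function(v, region) {
    v <- v[is.finite(v)]
    if (length(v) < min_pixels)
      stop(sprintf("insufficient data: %d valid pixels in %s (need >= %d)",
                   length(v), region, min_pixels), call. = FALSE)
    d <- density(v)
    d$x[which.max(d$y)]
  }
  if (is.null(spheroid_mask))
    return(list(background_peak_kPa = kde_mode(elast$E[elast$validity],
                                               "background")))
  stopifnot(all(dim(spheroid_mask) == dim(elast$E)))
  list(background_peak_kPa =
         kde_mode(elast$E[elast$validity & !spheroid_mask], "background"),
       spheroid_peak_kPa =
         kde_mode(elast$E[elast$validity & spheroid_mask], "spheroid"))
}

#' Render an elastogram to PNG
#'
#' Blue-to-red colour map over `display_range` (0 kPa blue to 20 kPa red
#' by default); invalid pixels render white.
#'
#' @param elast an `elastogram`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_elastogram <- function(elast, path) {
  stopifnot(inherits(elast, "elastogram"))
  pal <- colorRampPalette(c("blue", "cyan", "green", "yellow", "red"))(256)
  E <- elast$E
  rng <- elast$display_range
  idx <- pmax(1, pmin(256, 1 + floor((E - rng[1]) / diff(rng) * 255)))
  png(path, width = ncol(E) * 2, height = nrow(E) * 2)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); dev.off() })
  img <- t(idx[nrow(idx):1, , drop = FALSE])
  graphics::image(seq_len(nrow(img)), seq_len(ncol(img)), img,
                  col = pal, zlim = c(1, 256), axes = FALSE, xlab = "",
                  ylab = "", useRaster = TRUE)
  invisible(path)
}
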