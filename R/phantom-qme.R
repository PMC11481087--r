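#' Configuration for a synthetic QME phase-difference B-scan
#'
#' Forward model of compression optical coherence elastography under the
#' uniaxial-stress assumption: a compliant silicone layer sits on top of a
#' gel sample that may contain one stiff spherical (circular in the B-scan)
#' inclusion. A micro-scale compressive stress increment `applied_stress`
#' produces local strain `sigma0 / E`, axial displacement as the depth
#' integral of strain, and an inter-B-scan phase difference
#' `4 pi n u / lambda0` wrapped to (-pi, pi], with optional additive
#' Gaussian phase noise.
#'
#' Defaults mirror the acquisition this emulates: 1300 nm central
#' wavelength, refractive index 1.4, ~5% preload strain, 2.2 um lateral and
#' 2.4 um axial pixels, a stiff compliant layer over a soft gel whose
#' moduli sit at the soft-gel operating point (gel ~2.9 kPa, inclusion
#' ~6.4 kPa).
#'
#' @param layer_thicknesses `c(layer, sample)` in um.
#' @param layer_moduli `c(E_layer, E_gel)` in kPa.
#' @param inclusion `NULL` or list with `center` (`c(z, x)` um, z measured
#'   from the top of the sample), `radius` (um) and `E_kPa`.
#' @param applied_stress micro-scale stress increment sigma0, kPa.
#' @param preload_strain preload strain fraction (~0.05).
#' @param wavelength_nm OCT central wavelength, nm.
#' @param refractive_index sample refractive index.
#' @param pixel_size `c(axial, lateral)` pixel size, um.
#' @param lateral_extent lateral field of view, um.
#' @param phase_noise_sd additive Gaussian phase noise, rad.
#' @param seed integer RNG seed.
#' @return An object of class `qme_phantom_config`.
#' @seealso [generate_qme_pair()]
#' @export
qme_phantom_config <- function(layer_thicknesses = c(layer = 150, sample = 550),
                               layer_moduli = c(E_layer = 20, E_gel = 2.9),
                               inclusion = list(center = c(z = 275, x = 275),
                                                radius = 100, E_kPa = 6.4),
                               applied_stress = 0.01,
                               preload_strain = 0.05,
                               wavelength_nm = 1300,
                               refractive_index = 1.4,
                               pixel_size = c(axial = 2.4, lateral = 2.2),
                               lateral_extent = 550,
                               phase_noise_sd = 0,
                               seed = 1L) {
  check_positive(layer_thicknesses, "layer_thicknesses")
  check_positive(layer_moduli, "layer_moduli")
  check_positive(wavelength_nm, "wavelength_nm")
  check_positive(refractive_index, "refractive_index")
  check_positive(pixel_size, "pixel_size")
  check_positive(lateral_extent, "lateral_extent")
  if (applied_stress < 0) stop("`applied_stress` must be >= 0", call. = FALSE)
  if (phase_noise_sd < 0) stop("`phase_noise_sd` must be >= 0", call. = FALSE)
  if (preload_strain < 0 || preload_strain >= 1)
    stop("`preload_strain` must be in [0, 1)", call. = FALSE)
  if (!is.null(inclusion)) {
    check_positive(inclusion$radius, "inclusion$radius")
    check_positive(inclusion$E_kPa, "inclusion$E_kPa")
    if (length(inclusion$center) != 2L)
      stop("`inclusion$center` must be c(z, x) in um", call. = FALSE)
  }
  cfg <- list(layer_thicknesses = as.numeric(layer_thicknesses),
              layer_moduli = as.numeric(layer_moduli),
              inclusion = inclusion,
              applied_stress = applied_stress,
              preload_strain = preload_strain,
              wavelength_nm = wavelength_nm,
              refractive_index = refractive_index,
              pixel_size = as.numeric(pixel_size),
              lateral_extent = lateral_extent,
              phase_noise_sd = phase_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "qme_phantom_config"
  cfg
}

#' Generate a wrapped phase-difference B-scan with ground-truth maps
#'
#' Builds the modulus map (compliant layer on top, gel below, optional
#' circular inclusion), evaluates the uniaxial-stress forward model, wraps
#' the phase to (-pi, pi] and adds Gaussian phase noise. The generator
#' refuses configurations whose per-pixel displacement increment reaches
#' the aliasing bound `lambda0 / (4 n)` (phase increment >= pi), since such
#' data could not be unwrapped unambiguously.
#'
#' @param config a [qme_phantom_config()].
#' @return A list of class `qme_phantom` with `phase` (wrapped phase
#'   difference, matrix `c(nz, nx)`), `truth_E` (kPa), `truth_strain`,
#'   `layer_band` (axial pixel range of the compliant layer), `meta`
#'   (an [acquisition_meta()]) and `config`.
#' @export
generate_qme_pair <- function(config) {
  stopifnot(inherits(config, "qme_phantom_config"))
  cfg <- config
  dz <- cfg$pixel_size[1]
  dx <- cfg$pixel_size[2]
  total_depth <- sum(cfg$layer_thicknesses)
  nz <- as.integer(ceiling(total_depth / dz))
  nx <- as.integer(ceiling(cfg$lateral_extent / dx))
  zc <- (seq_len(nz) - 0.5) * dz            # depth from top of layer
  xc <- (seq_len(nx) - 0.5) * dx

  E <- matrix(cfg$layer_moduli[2], nz, nx)
  in_layer <- zc <= cfg$layer_thicknesses[1]
  E[in_layer, ] <- cfg$layer_moduli[1]
  if (!is.null(cfg$inclusion)) {
    cen_z <- cfg$layer_thicknesses[1] + cfg$inclusion$center[1]
    cen_x <- cfg$inclusion$center[2]
    d2 <- outer((zc - cen_z)^2, (xc - cen_x)^2, "+")
    E[d2 <= cfg$inclusion$radius^2] <- cfg$inclusion$E_kPa
  }

  strain <- cfg$applied_stress / E
  # aliasing invariant: per-pixel displacement increment < lambda0 / (4 n)
  bound_um <- cfg$wavelength_nm / (4 * cfg$refractive_index) / 1000
  max_inc <- max(strain) * dz
  if (max_inc >= bound_um)
    stop(sprintf(paste0(
      "aliased configuration refused: per-pixel displacement increment ",
      "%.1f nm reaches the %.1f nm wrap-ambiguity bound lambda0/(4n); ",
      "reduce applied_stress, or keep every modulus above %.3g kPa"),
      max_inc * 1000, bound_um * 1000,
      cfg$applied_stress * dz / bound_um), call. = FALSE)

  u <- apply(strain * dz, 2, cumsum)        # um, depth integral of strain
  phase <- 4 * pi * cfg$refractive_index * (u * 1000) / cfg$wavelength_nm
  phase <- wrap_phase(phase)
  if (cfg$phase_noise_sd > 0)
    phase <- with_seed(cfg$seed,
      wrap_phase(phase + matrix(rnorm(length(phase), 0, cfg$phase_noise_sd),
                                nz, nx)))

  structure(list(
    phase = phase,
    truth_E = E,
    truth_strain = strain,
    layer_band = range(which(in_layer)),
    meta = acquisition_meta(wavelength_nm = cfg$wavelength_nm,
                            refractive_index = cfg$refractive_index,
                            pixel_size = cfg$pixel_size),
    config = cfg), class = "qme_phantom")
}
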