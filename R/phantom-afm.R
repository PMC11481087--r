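#' Configuration for a synthetic AFM indentation force curve
#'
#' Pyramid-indenter approach curve: zero force until the tip reaches
#' `contact_point` along the approach axis, then the Sneddon-type pyramid
#' contact law `F = C(theta, nu) * E * delta^2` (see [pyramid_constant()])
#' for indentation `delta`, with additive Gaussian force noise. Defaults
#' follow soft-hydrogel practice: incompressible gel (`nu = 0.5`),
#' 35 degree pyramid half-angle, indentation depths producing forces on
#' the scale of a ~2 nN trigger.
#'
#' @param E_true true Young's modulus, kPa.
#' @param poisson_ratio Poisson's ratio in (0, 0.5].
#' @param tip_half_angle pyramid face half-angle, degrees, in (0, 90).
#' @param contact_point separation at which contact begins, um.
#' @param max_indentation maximum indentation depth beyond contact, um.
#' @param n_samples number of samples along the approach axis (>= 20).
#' @param force_noise_sd additive Gaussian force noise, nN.
#' @param seed integer RNG seed.
#' @return An object of class `afm_curve_config`.
#' @export
afm_curve_config <- function(E_true = 10,
                             poisson_ratio = 0.5,
                             tip_half_angle = 35,
                             contact_point = 2,
                             max_indentation = 0.6,
                             n_samples = 200L,
                             force_noise_sd = 0,
                             seed = 1L) {
  check_positive(E_true, "E_true")
  check_positive(max_indentation, "max_indentation")
  if (poisson_ratio <= 0 || poisson_ratio > 0.5)
    stop("`poisson_ratio` must be in (0, 0.5]", call. = FALSE)
  if (tip_half_angle <= 0 || tip_half_angle >= 90)
    stop("`tip_half_angle` must be in (0, 90) degrees", call. = FALSE)
  if (contact_point < 0) stop("`contact_point` must be >= 0", call. = FALSE)
  if (n_samples < 20) stop("`n_samples` must be >= 20", call. = FALSE)
  if (force_noise_sd < 0)
    stop("`force_noise_sd` must be >= 0", call. = FALSE)
  cfg <- list(E_true = E_true, poisson_ratio = poisson_ratio,
              tip_half_angle = tip_half_angle, contact_point = contact_point,
              max_indentation = max_indentation,
              n_samples = as.integer(n_samples),
              force_noise_sd = force_noise_sd, seed = as.integer(seed))
  class(cfg) <- "afm_curve_config"
  cfg
}

#' Generate a synthetic AFM force curve
#'
#' Samples the approach axis uniformly from 0 to
#' `contact_point + max_indentation` and evaluates the same pyramid contact
#' model the fitter assumes ([pyramid_constant()]), so a zero-noise
#' round-trip through [fit_young_modulus()] recovers `E_true` exactly.
#'
#' @param config an [afm_curve_config()].
#' @param position_mm optional position along the stiffness gradient, mm.
#' @param replicate optional replicate index.
#' @return A [force_curve()] with the generating config in
#'   `attr(, "config")`.
#' @export
generate_afm_curve <- function(config, position_mm = NA_real_,
                               replicate = NA_integer_) {
  stopifnot(inherits(config, "afm_curve_config"))
  cfg <- config
  # the grid contains the contact point exactly, so zero-noise curves are
  # the contact model evaluated on-grid and round-trips are exact
  total <- cfg$contact_point + cfg$max_indentation
  n_pre <- max(5L, round(cfg$n_samples * cfg$contact_point / total))
  n_pre <- min(n_pre, cfg$n_samples - 15L)
  sep <- c(seq(0, cfg$contact_point, length.out = n_pre),
           seq(cfg$contact_point, total,
               length.out = cfg$n_samples - n_pre + 1L)[-1])
  delta <- pmax(0, sep - cfg$contact_point)
  C <- pyramid_constant(cfg$tip_half_angle, cfg$poisson_ratio)
  force <- C * cfg$E_true * delta^2
  if (cfg$force_noise_sd > 0)
    force <- with_seed(cfg$seed,
                       force + rnorm(length(force), 0, cfg$force_noise_sd))
  curve <- force_curve(sep, force, position_mm = position_mm,
                       replicate = replicate)
  attr(curve, "config") <- cfg
  curve
}
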