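#' Configuration for a synthetic spheroid growth time series
#'
#' Projected-area growth following `A(t) = A0 * exp(k * t)` with
#' multiplicative Gaussian noise, emulating live-imaging time courses in
#' which spheroids in soft matrix grow exponentially faster than in stiff.
#' Defaults describe a 10-day culture sampled daily from a single-cell
#' footprint (~150 um^2).
#'
#' @param A0 initial projected area, um^2.
#' @param rate exponential growth rate `k`, per day.
#' @param times acquisition times, days, strictly increasing.
#' @param noise_sd multiplicative noise SD as a fraction of signal.
#' @param seed integer RNG seed.
#' @return An object of class `growth_series_config`.
#' @export
growth_series_config <- function(A0 = 150, rate = 0.4, times = 0:10,
                                 noise_sd = 0.05, seed = 1L) {
  check_positive(A0, "A0")
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  cfg <- list(A0 = A0, rate = rate, times = as.numeric(times),
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "growth_series_config"
  cfg
}

#' Generate a synthetic growth series
#'
#' @param config a [growth_series_config()].
#' @return A data frame with columns `time_days` and `area_um2`
#'   (strictly positive), with the config in `attr(, "config")`.
#' @export
generate_growth_series <- function(config) {
  stopifnot(inherits(config, "growth_series_config"))
  cfg <- config
  areas <- cfg$A0 * exp(cfg$rate * cfg$times)
  if (cfg$noise_sd > 0)
    areas <- with_seed(cfg$seed,
      areas * (1 + rnorm(length(areas), 0, cfg$noise_sd)))
  areas <- pmax(areas, .Machine$double.eps)
  out <- data.frame(time_days = cfg$times, area_um2 = areas)
  attr(out, "config") <- cfg
  out
}
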