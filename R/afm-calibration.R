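#' Pyramid-indenter contact constant
#'
#' Sneddon-type contact law for a four-sided pyramidal tip on an elastic
#' half-space: `F = C(theta, nu) * E * delta^2` with
#' `C = tan(theta) / (sqrt(2) * (1 - nu^2))`. With E in kPa and delta in
#' um, C carries units nN um^-2 kPa^-1 and equals the dimensionless value
#' returned here (1 kPa = 1 nN/um^2). The generator and the fitter share
#' this single forward model.
#'
#' @param half_angle_deg pyramid face half-angle, degrees.
#' @param poisson_ratio Poisson's ratio.
#' @return The contact constant C (> 0).
#' @export
pyramid_constant <- function(half_angle_deg = 35, poisson_ratio = 0.5) {
  if (half_angle_deg <= 0 || half_angle_deg >= 90)
    stop("`half_angle_deg` must be in (0, 90)", call. = FALSE)
  if (poisson_ratio <= 0 || poisson_ratio > 0.5)
    stop("`poisson_ratio` must be in (0, 0.5]", call. = FALSE)
  tan(half_angle_deg * pi / 180) / (sqrt(2) * (1 - poisson_ratio^2))
}

#' Indenter model for Young's modulus fitting
#'
#' @param half_angle_deg pyramid face half-angle, degrees (default 35).
#' @param poisson_ratio Poisson's ratio (default 0.5, incompressible gel).
#' @return An object of class `indenter_model` with the derived contact
#'   constant `C`.
#' @export
indenter_model <- function(half_angle_deg = 35, poisson_ratio = 0.5) {
  structure(list(half_angle_deg = half_angle_deg,
                 poisson_ratio = poisson_ratio,
                 C = pyramid_constant(half_angle_deg, poisson_ratio)),
            class = "indenter_model")
}

#' Construct an AFM force curve
#'
#' @param separation_um monotone approach-axis separation, um.
#' @param force_nN measured force, nN.
#' @param position_mm position along the stiffness gradient, mm.
#' @param replicate replicate index at that position.
#' @return A data frame of class `force_curve` with columns
#'   `separation_um`, `force_nN` and metadata attributes.
#' @export
force_curve <- function(separation_um, force_nN,
                        position_mm = NA_real_, replicate = NA_integer_) {
  if (length(separation_um) != length(force_nN))
    stop("separation and force must have equal length", call. = FALSE)
  if (length(separation_um) < 20)
    stop("a force curve needs >= 20 samples", call. = FALSE)
  if (any(diff(separation_um) <= 0))
    stop("`separation_um` must be strictly increasing", call. = FALSE)
  out <- data.frame(separation_um = as.numeric(separation_um),
                    force_nN = as.numeric(force_nN))
  attr(out, "position_mm") <- position_mm
  attr(out, "replicate") <- replicate
  class(out) <- c("force_curve", "data.frame")
  out
}

#' Detect the tip-sample contact point of a force curve
#'
#' Change-point search: for every candidate separation, the curve is fit
#' as a flat baseline before contact plus the quadratic pyramid contact
#' law beyond it (`F = b0 + A * (s - c)^2` for `s > c`), and the candidate
#' minimising the residual sum of squares wins. A curve whose force range
#' never rises above the baseline noise (5 robust SDs) is rejected as
#' having no contact.
#'
#' @param curve a [force_curve()].
#' @return The separation (um) at which sustained force rise begins.
#' @export
detect_contact_point <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  s <- curve$separation_um
  f <- curve$force_nN
  n <- length(s)
  rise <- max(f) - median(f)
  if (rise <= 5 * mad(f) + 1e-12)
    stop("no contact detected: force never rises above baseline noise",
         call. = FALSE)
  # need a handful of points on each side of the candidate
  cand <- seq(3L, n - 5L)
  best <- NULL
  best_rss <- Inf
  for (i in cand) {
    q <- pmax(0, s - s[i])^2
    X <- cbind(1, q)
    fit <- stats::lm.fit(X, f)
    rss <- sum(fit$residuals^2)
    A <- fit$coefficients[2]
    if (rss < best_rss && !is.na(A) && A > 0) {
      best_rss <- rss
      best <- i
    }
  }
  rss_flat <- sum((f - mean(f))^2)
  if (is.null(best) || best_rss >= rss_flat)
    stop("no contact detected: no change point improves on a flat fit",
         call. = FALSE)
  s[best]
}

#' Fit a Young's modulus to the post-contact portion of a force curve
#'
#' Least squares of the pyramid contact law `F = C * E * delta^2` through
#' the origin over post-contact samples, after subtracting the pre-contact
#' baseline force.
#'
#' @param curve a [force_curve()].
#' @param indenter an [indenter_model()].
#' @param contact contact-point separation, um (e.g. from
#'   [detect_contact_point()]).
#' @return A list with `E_kPa` (> 0), `r2` of the quadratic fit, `contact`
#'   and `n_post` (post-contact sample count).
#' @export
fit_young_modulus <- function(curve, indenter = indenter_model(),
                              contact) {
  stopifnot(inherits(curve, "force_curve"),
            inherits(indenter, "indenter_model"))
  s <- curve$separation_um
  f <- curve$force_nN
  if (contact < min(s) || contact > max(s))
    stop("contact point lies outside the curve domain", call. = FALSE)
  post <- s > contact
  if (sum(post) < 10)
    stop(sprintf("insufficient data: %d post-contact samples (need >= 10)",
                 sum(post)), call. = FALSE)
  baseline <- if (any(!post)) mean(f[!post]) else 0
  delta <- s[post] - contact
  y <- f[post] - baseline
  E <- sum(y * delta^2) / (indenter$C * sum(delta^4))
  if (!is.finite(E) || E <= 0)
    stop("fitted modulus is non-positive; curve is not a contact curve",
         call. = FALSE)
  fitted <- indenter$C * E * delta^2
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum((y - fitted)^2) / sst)) else 1
  list(E_kPa = E, r2 = r2, contact = contact, n_post = sum(post))
}

#' Fit the linear position-to-stiffness gradient map
#'
#' Replicate measurements at the same position (triplet indentations) are
#' averaged first, then an ordinary least-squares line `E = slope * x +
#' intercept` is fit across positions.
#'
#' @param points data frame with columns `position_mm` and `E_kPa`
#'   (optionally `replicate`).
#' @return An object of class `gradient_calibration` with `slope` (kPa/mm),
#'   `intercept` (kPa), `r2`, `domain` (range of positions, mm), `points`
#'   (the replicate-averaged points) and `n`.
#' @export
fit_linear_gradient <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("position_mm", "E_kPa") %in% names(points)))
  avg <- stats::aggregate(E_kPa ~ position_mm, data = points, FUN = mean)
  if (nrow(avg) < 2)
    stop("insufficient data: need >= 2 distinct positions", call. = FALSE)
  fit <- lm(E_kPa ~ position_mm, data = avg)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 slope_se = sm$coefficients[2, 2],
                 domain = range(avg$position_mm),
                 points = avg,
                 n = nrow(avg)),
            class = "gradient_calibration")
}

#' Evaluate the gradient calibration at a position
#'
#' Affine interpolation only: positions outside the calibrated domain are
#' refused rather than extrapolated.
#'
#' @param cal a [fit_linear_gradient()] result.
#' @param position_mm position(s) along the gradient, mm.
#' @return Stiffness in kPa.
#' @export
stiffness_at <- function(cal, position_mm) {
  stopifnot(inherits(cal, "gradient_calibration"))
  tol <- 1e-9 * max(1, diff(cal$domain))
  bad <- position_mm < cal$domain[1] - tol | position_mm > cal$domain[2] + tol
  if (any(bad))
    stop(sprintf(
      "position %s mm outside the calibrated domain [%g, %g] mm (no extrapolation)",
      paste(signif(position_mm[bad], 4), collapse = ", "),
      cal$domain[1], cal$domain[2]), call. = FALSE)
  cal$slope * position_mm + cal$intercept
}

#' @export
print.gradient_calibration <- function(x, ...) {
  cat(sprintf(
    "stiffness gradient: E = %.3f kPa/mm * x + %.3f kPa  (r2 = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r2, x$n))
  cat(sprintf("  domain: %g-%g mm -> %.1f-%.1f kPa\n",
              x$domain[1], x$domain[2],
              stiffness_at(x, x$domain[1]), stiffness_at(x, x$domain[2])))
  invisible(x)
}
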