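# background estimate for a marker channel: median over an annulus of
# given physical width dilated just outside the mask; falls back to a
# global low percentile when the annulus is empty (mask touches borders)
marker_background <- function(marker, mask, voxel_size, annulus_um = 5,
                              fallback_quantile = 0.2) {
  d_out <- distance_transform(!mask, voxel_size)  # outside: distance to mask
  annulus <- !mask & d_out <= annulus_um & d_out > 0
  if (!any(annulus)) {
    warning("background annulus empty (mask touches the stack border); ",
            "falling back to a global low percentile")
    return(unname(quantile(marker, fallback_quantile)))
  }
  median(marker[annulus])
}

#' Background-subtracted mean marker intensity of a spheroid
#'
#' Mean of the marker channel inside the spheroid mask minus the median
#' of a surrounding annulus of the given width, floored at zero. With
#' `erode_um > 0` the mean is taken over the mask eroded by that depth:
#' the optical PSF dilutes the outermost shell of the spheroid into the
#' background, so an interior mean (erode by about 2 PSF sigma) estimates
#' the undiluted concentration.
#'
#' @param marker marker-channel 3D array.
#' @param spheroid_mask logical spheroid mask.
#' @param voxel_size voxel size `c(dx, dy, dz)`, um.
#' @param annulus_um background annulus width, um.
#' @param erode_um interior erosion depth, um (0 = plain mask mean).
#' @return Non-negative mean intensity (background-subtracted).
#' @export
mean_marker_intensity <- function(marker, spheroid_mask, voxel_size,
                                  annulus_um = 5, erode_um = 0) {
  stopifnot(all(dim(marker) == dim(spheroid_mask)))
  if (!any(spheroid_mask)) stop("spheroid mask is empty", call. = FALSE)
  bg <- marker_background(marker, spheroid_mask, voxel_size, annulus_um)
  region <- spheroid_mask
  if (erode_um > 0) {
    core <- region & distance_transform(region, voxel_size) > erode_um
    if (any(core)) region <- core
  }
  max(0, mean(marker[region]) - bg)
}

#' Nuclear/cytoplasmic marker intensity ratio
#'
#' Mean background-subtracted marker intensity over nuclear voxels
#' divided by the mean over cytoplasmic voxels (spheroid minus nuclei) —
#' the translocation readout used for YAP. Because the optical PSF mixes
#' the two compartments at their shared boundary, both compartments are
#' eroded by `erode_um` (about one PSF sigma) before averaging; set it to
#' 0 for the raw voxel means.
#'
#' @param marker marker-channel 3D array.
#' @param nuclei_labels integer nuclei label array.
#' @param spheroid_mask logical spheroid mask.
#' @param voxel_size voxel size `c(dx, dy, dz)`, um.
#' @param annulus_um background annulus width, um.
#' @param erode_um boundary exclusion depth, um.
#' @return The nuclear/cytoplasmic ratio (> 0).
#' @export
yap_nuc_cyto_ratio <- function(marker, nuclei_labels, spheroid_mask,
                               voxel_size, annulus_um = 5, erode_um = 1) {
  stopifnot(all(dim(marker) == dim(spheroid_mask)),
            all(dim(nuclei_labels) == dim(spheroid_mask)))
  nuc <- nuclei_labels > 0L & spheroid_mask
  cyto <- spheroid_mask & !nuc
  if (!any(nuc)) stop("no nuclear voxels", call. = FALSE)
  if (!any(cyto)) stop("no cytoplasmic voxels", call. = FALSE)
  if (erode_um > 0) {
    nuc_e <- nuc & distance_transform(nuc, voxel_size) > erode_um
    cyto_e <- cyto & distance_transform(cyto, voxel_size) > erode_um
    # fall back to the raw compartments if erosion empties either
    if (any(nuc_e) && any(cyto_e)) {
      nuc <- nuc_e
      cyto <- cyto_e
    }
  }
  bg <- marker_background(marker, spheroid_mask, voxel_size, annulus_um)
  m_cyto <- mean(marker[cyto]) - bg
  if (m_cyto <= 0)
    stop("undefined ratio: cytoplasmic mean is not above background",
         call. = FALSE)
  (mean(marker[nuc]) - bg) / m_cyto
}

#' Fit a marker expression trend against stiffness or volume
#'
#' Linear trends are fit by ordinary least squares; exponential trends
#' `I = a * exp(b * x)` by nonlinear least squares initialised from the
#' log-linear OLS solution. `r2` is computed on the intensity scale in
#' both cases, and the non-zero-slope p-value comes from the t-test on
#' the linear slope or the asymptotic test of `b = 0`.
#'
#' @param measurements data frame with columns `mean_intensity` and the
#'   chosen x column (`stiffness_kPa` or `spheroid_volume_um3`).
#' @param x_kind `"stiffness"` or `"volume"`.
#' @param model `"linear"` or `"exponential"`.
#' @param marker_name optional marker label carried into the result.
#' @return An object of class `expression_trend` with `params`, `r2`,
#'   `p_nonzero_slope`, `n`, `x_kind`, `model` and `marker_name`.
#' @export
fit_expression_trend <- function(measurements,
                                 x_kind = c("stiffness", "volume"),
                                 model = c("linear", "exponential"),
                                 marker_name = NA_character_) {
  x_kind <- match.arg(x_kind)
  model <- match.arg(model)
  xcol <- switch(x_kind, stiffness = "stiffness_kPa",
                 volume = "spheroid_volume_um3")
  stopifnot(is.data.frame(measurements),
            all(c(xcol, "mean_intensity") %in% names(measurements)))
  x <- measurements[[xcol]]
  y <- measurements$mean_intensity
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3)
    stop("need >= 3 measurements to fit a trend", call. = FALSE)

  if (model == "linear") {
    tf <- nonzero_slope_test(x, y)
    params <- list(slope = tf$slope, intercept = tf$intercept)
    r2 <- tf$r2
    p <- tf$p_nonzero_slope
  } else {
    if (any(y <= 0))
      stop(paste("exponential model requires positive intensities;",
                 "use the linear model"), call. = FALSE)
    init <- lm(log(y) ~ x)
    start <- list(a = exp(unname(coef(init)[1])),
                  b = unname(coef(init)[2]))
    fit <- nls(y ~ a * exp(b * x), start = start,
               control = nls.control(maxiter = 200, warnOnly = TRUE))
    cf <- summary(fit)$coefficients
    params <- list(amplitude = unname(cf["a", 1]), rate = unname(cf["b", 1]))
    fitted_y <- predict(fit)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) max(0, min(1, 1 - sum((y - fitted_y)^2) / sst)) else 1
    p <- unname(cf["b", 4])
  }
  structure(list(marker_name = marker_name, x_kind = x_kind, model = model,
                 params = params, r2 = r2, p_nonzero_slope = p,
                 n = length(x)),
            class = "expression_trend")
}

#' @export
print.expression_trend <- function(x, ...) {
  lab <- if (is.na(x$marker_name)) "trend" else x$marker_name
  cat(sprintf("%s ~ %s [%s]: %s; r2 = %.3f, p(slope=0) = %.3g, n = %d\n",
              lab, x$x_kind, x$model,
              paste(sprintf("%s = %.4g", names(x$params),
                            unlist(x$params)),
                    collapse = ", "),
              x$r2, x$p_nonzero_slope, x$n))
  invisible(x)
}
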