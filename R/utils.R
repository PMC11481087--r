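`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the prior
#' RNG state afterwards, making every generator a pure function of
#' (config, seed).
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage sub-seed from a global seed
#'
#' Deterministic counter scheme: stage `k` of a run seeded with `seed`
#' uses `(seed + k * 10007) mod (2^31 - 1)`, kept strictly positive, so
#' stage-level reruns are reproducible in isolation.
#'
#' @param seed integer global seed.
#' @param k stage counter (0, 1, 2, ...).
#' @return integer sub-seed.
#' @export
stage_seed <- function(seed, k) {
  s <- (as.double(seed) + as.double(k) * 10007) %% (2^31 - 1)
  as.integer(s + (s == 0))
}

#' Wrap phase to the half-open interval (-pi, pi]
#' @param phi numeric phase in radians.
#' @return wrapped phase.
#' @export
wrap_phase <- function(phi) {
  phi - 2 * pi * ceiling((phi - pi) / (2 * pi))
}

# Otsu's threshold on a numeric vector (maximises between-class variance
# over a fixed-width histogram).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + as.integer((x - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# dims of a (nz, ny, nx) array as integer vector; promotes 2D to z = 1 slab
arr_dims <- function(a) {
  d <- dim(a)
  if (is.null(d)) stop("expected an array or matrix", call. = FALSE)
  if (length(d) == 2L) d <- c(1L, d)
  as.integer(d)
}

as_slab <- function(a) {
  if (length(dim(a)) == 2L) array(a, dim = c(1L, dim(a))) else a
}

# voxel_size (dx, dy, dz) -> spacing aligned with array dims (dz, dy, dx)
spacing_zyx <- function(voxel_size) {
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  rev(as.numeric(voxel_size))
}

check_positive <- function(value, name) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  invisible(value)
}

# Gaussian blur of a 3D array with per-axis physical sigma (micrometres)
blur_physical <- function(arr, sigma_um, voxel_size) {
  if (all(sigma_um <= 0)) return(arr)
  sp <- spacing_zyx(voxel_size)
  sig <- rep_len(sigma_um, 3L)
  out <- cpp_gaussian_blur3d(as.numeric(arr), arr_dims(arr), rev(sig) / sp)
  array(out, dim = dim(arr))
}

# Euclidean distance transform (micrometres) of a logical mask:
# distance of foreground voxels to the nearest background voxel.
distance_transform <- function(mask, voxel_size) {
  d2 <- cpp_edt_sq(as.integer(mask), arr_dims(mask), spacing_zyx(voxel_size))
  array(sqrt(d2), dim = dim(mask))
}

# Binary closing with a physical radius via two distance transforms.
binary_closing <- function(mask, radius_um, voxel_size) {
  if (radius_um <= 0) return(mask)
  dil <- distance_transform(!mask, voxel_size) <= radius_um | mask
  ero <- distance_transform(dil, voxel_size) > radius_um
  array(ero, dim = dim(mask))
}

label_components <- function(mask, connectivity = 26L) {
  lab <- cpp_label3d(as.integer(mask), arr_dims(mask), as.integer(connectivity))
  array(lab, dim = dim(mask))
}

fill_holes <- function(mask) {
  array(cpp_fill_holes(as.integer(mask), arr_dims(mask)) > 0L, dim = dim(mask))
}
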