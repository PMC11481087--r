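# shared fixtures and independent oracles used across test files

# a fast phantom for unit tests: six 100 um^3 nuclei in a 1000 um^3/cell
# spheroid at isotropic 0.5 um voxels (~150k voxels)
small_phantom_config <- function(seed = 1L, ...) {
  args <- list(...)
  do.call(spheroid_phantom_config, utils::modifyList(list(
    n_nuclei = 6L, nuclear_volume = 100, cell_volume = 1000,
    voxel_size = c(0.5, 0.5, 0.5), blur_sigma = 0.5, seed = seed), args))
}

# brute-force Gaussian-weighted median at one voxel of a 3D array
# (independent of the C++ kernel: plain R loops)
bf_weighted_median <- function(arr, at, radius, sigma) {
  d <- dim(arr)
  vals <- numeric(0)
  wts <- numeric(0)
  for (dk in -radius:radius) for (dj in -radius:radius)
    for (di in -radius:radius) {
      p <- at + c(di, dj, dk)
      if (any(p < 1) || any(p > d)) next
      vals <- c(vals, arr[p[1], p[2], p[3]])
      wts <- c(wts, exp(-0.5 * (di^2 + dj^2 + dk^2) / sigma^2))
    }
  o <- order(vals)
  vals <- vals[o]
  wts <- wts[o]
  vals[which(cumsum(wts) >= 0.5 * sum(wts))[1]]
}

# permutation p-value for the non-zero-slope test (two-sided, |slope|)
perm_slope_p <- function(x, y, B = 10000, seed = 1) {
  obs <- abs(coef(lm(y ~ x))[2])
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    if (abs(coef(lm(sample(y) ~ x))[2]) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# brute-force Kruskal-Wallis H on a list of groups (hand ranking,
# no tie correction needed for distinct values)
bf_kruskal_H <- function(groups) {
  v <- unlist(groups)
  n <- length(v)
  r <- rank(v)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(groups), function(g) {
      Rg <- sum(r[idx == g])
      Rg^2 / sum(idx == g)
    }, numeric(1))) - 3 * (n + 1)
  H
}

# a synthetic two-channel grid holding one perfect ball (radius um) for
# segmentation geometry tests
ball_grid <- function(radius_um = 15, voxel = c(0.5, 0.5, 0.5),
                      pad_um = 3) {
  sp <- rev(voxel)
  dims <- as.integer(ceiling(2 * (radius_um + pad_um) / sp))
  ctr <- dims * sp / 2
  zc <- (seq_len(dims[1]) - 0.5) * sp[1]
  yc <- (seq_len(dims[2]) - 0.5) * sp[2]
  xc <- (seq_len(dims[3]) - 0.5) * sp[3]
  d2 <- outer(outer((zc - ctr[1])^2, (yc - ctr[2])^2, "+"),
              (xc - ctr[3])^2, "+")
  mask <- d2 <= radius_um^2
  voxel_grid(list(actin = array(as.numeric(mask), dim = dims),
                  nuclei = array(0, dim = dims)),
             voxel)
}
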