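test_that("weighted median filter matches a brute-force oracle", {
  arr <- with_seed(11, array(runif(20 * 18 * 16), dim = c(20, 18, 16)))
  out <- prefilter_nuclei_channel(arr, radius = 2L, sigma = 1.5)
  at <- with_seed(12, replicate(5, sapply(dim(arr), function(n)
    sample(n, 1))))
  for (i in 1:5) {
    p <- at[, i]
    expect_equal(out[p[1], p[2], p[3]],
                 bf_weighted_median(arr, p, 2L, 1.5))
  }
  # range containment
  expect_gte(min(out), min(arr))
  expect_lte(max(out), max(arr))
})

test_that("weighted median leaves constants and kills hot voxels", {
  const <- array(3.7, dim = c(8, 8, 8))
  expect_equal(prefilter_nuclei_channel(const, radius = 2L), const)
  hot <- array(0, dim = c(9, 9, 9))
  hot[5, 5, 5] <- 100
  filt <- prefilter_nuclei_channel(hot, radius = 2L, sigma = 1)
  expect_identical(filt[5, 5, 5], bf_weighted_median(hot, c(5, 5, 5), 2L, 1))
  expect_identical(filt[5, 5, 5], 0)
})

test_that("spheroid gating recovers an analytic sphere volume within 2%", {
  grid <- ball_grid(radius_um = 15)
  mask <- segment_spheroid(grid)
  vol <- sum(mask) * prod(grid$voxel_size)
  expect_lt(abs(vol - 4 / 3 * pi * 15^3) / (4 / 3 * pi * 15^3), 0.02)
  # one 26-connected component
  expect_identical(max(spheromech:::label_components(mask, 26L)), 1L)
})

test_that("empty stacks raise a no-spheroid error", {
  grid <- voxel_grid(list(actin = array(0, dim = c(10, 10, 10))),
                     c(0.5, 0.5, 0.5))
  expect_error(segment_spheroid(grid), "no spheroid detected")
})

test_that("the larger of two disjoint spheroids is kept with a warning", {
  g1 <- ball_grid(radius_um = 12, pad_um = 8)
  d <- dim(g1$channels$actin)
  two <- array(0, dim = d)
  two[] <- g1$channels$actin
  # plant a smaller second ball in a corner
  zc <- (seq_len(d[1]) - 0.5) * 0.5
  yc <- (seq_len(d[2]) - 0.5) * 0.5
  xc <- (seq_len(d[3]) - 0.5) * 0.5
  d2 <- outer(outer((zc - 4)^2, (yc - 4)^2, "+"), (xc - 4)^2, "+")
  two[d2 <= 3^2] <- 1
  grid <- voxel_grid(list(actin = two), c(0.5, 0.5, 0.5))
  expect_warning(mask <- segment_spheroid(grid), "discarded 1")
  vol <- sum(mask) * prod(grid$voxel_size)
  expect_lt(abs(vol - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3), 0.03)
})

test_that("well-separated nuclei are counted exactly with close centroids", {
  cfg <- small_phantom_config(seed = 21, n_nuclei = 10L, cell_volume = 1200)
  ph <- generate_spheroid_stack(cfg)
  grid <- voxel_grid(ph$stack, cfg$voxel_size)
  mask <- segment_spheroid(grid)
  labs <- segment_nuclei(prefilter_nuclei_channel(grid), mask,
                         cfg$voxel_size)
  expect_identical(max(labs), 10L)
  # centroids within one voxel (0.87 um diagonal) of the truth
  sp <- rev(cfg$voxel_size)
  cents <- t(sapply(seq_len(10), function(l) {
    idx <- which(labs == l)
    colMeans(sweep(arrayInd(idx, dim(labs)) - 0.5, 2, sp, `*`))
  }))
  truth <- ph$truth$nuclei_centroids
  for (i in seq_len(10)) {
    d <- sqrt(rowSums(sweep(truth, 2, cents[i, ])^2))
    expect_lt(min(d), sqrt(sum(cfg$voxel_size^2)))
  }
})

test_that("touching nuclei pairs are split by the watershed", {
  cfg <- small_phantom_config(seed = 5, n_nuclei = 2L, cell_volume = 2500,
                              touching_pairs = TRUE)
  ph <- generate_spheroid_stack(cfg)
  # the noiseless pair really touches: one connected foreground blob
  blob <- spheromech:::label_components(ph$truth$nuclei_labels > 0, 26L)
  expect_identical(max(blob), 1L)
  grid <- voxel_grid(ph$stack, cfg$voxel_size)
  mask <- segment_spheroid(grid)
  labs <- segment_nuclei(prefilter_nuclei_channel(grid), mask,
                         cfg$voxel_size, min_sep_um = 3)
  expect_identical(max(labs), 2L)
})

test_that("nuclei counts are recovered under realistic noise", {
  # Poisson shot noise + Gaussian read noise at signal-to-background 10,
  # 25 seeds (scaled down from 50 to keep the default run fast; the
  # acceptance suite runs the full 50)
  counts <- vapply(1:25, function(s) {
    cfg <- small_phantom_config(seed = s, n_nuclei = 8L,
                                noise = list(gaussian_sd = 0.1,
                                             poisson_scale = 100))
    ph <- generate_spheroid_stack(cfg)
    grid <- voxel_grid(ph$stack, cfg$voxel_size)
    mask <- segment_spheroid(grid)
    labs <- segment_nuclei(prefilter_nuclei_channel(grid), mask,
                           cfg$voxel_size)
    max(labs)
  }, integer(1))
  expect_lte(mean(abs(counts - 8L)) / 8, 0.05)
})

test_that("morphometry arithmetic and additivity are exact", {
  mask <- array(FALSE, dim = c(10, 10, 10))
  mask[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  labs <- array(0L, dim = dim(mask))
  labs[2:5, 2:5, 2:5] <- rep(1:4, each = 16)
  rec <- compute_morphometry(mask, labs, c(0.3, 0.3, 0.5))
  expect_equal(rec$spheroid_volume_um3, 1000 * 0.045)
  expect_equal(rec$nuclei_count, 4L)
  expect_equal(rec$cell_volume_um3, rec$spheroid_volume_um3 / 4)
  expect_equal(rec$cytoplasmic_volume_um3,
               rec$spheroid_volume_um3 - rec$nuclear_volume_um3)

  # empty segmentation refuses a per-cell volume
  expect_error(compute_morphometry(mask, array(0L, dim = dim(mask)),
                                   c(0.3, 0.3, 0.5)),
               "no nuclei")
})

test_that("volumes scale by the exact voxel Jacobian", {
  cfg <- small_phantom_config(seed = 9)
  ph <- generate_spheroid_stack(cfg)
  r1 <- compute_morphometry(ph$truth$spheroid_mask, ph$truth$nuclei_labels,
                            c(0.5, 0.5, 0.5))
  r2 <- compute_morphometry(ph$truth$spheroid_mask, ph$truth$nuclei_labels,
                            c(1.0, 1.0, 0.5))
  expect_equal(r2$spheroid_volume_um3, 4 * r1$spheroid_volume_um3)
  expect_equal(r2$nuclear_volume_um3, 4 * r1$nuclear_volume_um3)
})

test_that("central projection window follows the axial step arithmetic", {
  # 150 slices at 0.5 um with the object centred at slice 75: a 30 um
  # window projects slices 45..105
  arr <- array(0, dim = c(150, 20, 20))
  arr[75, 10, 10] <- 5
  arr[44, 10, 10] <- 9   # just outside the window
  arr[46, 11, 11] <- 7
  mask <- array(FALSE, dim = dim(arr))
  mask[75, , ] <- TRUE
  grid <- voxel_grid(list(nuclei = arr), c(0.3, 0.3, 0.5))
  mip <- central_mip(grid, 30, mask)
  expect_identical(dim(mip$nuclei), c(20L, 20L))
  expect_equal(mip$nuclei[10, 10], 5)   # slice 44 value 9 excluded
  expect_equal(mip$nuclei[11, 11], 7)
  # constant stack projects to the constant
  cgrid <- voxel_grid(list(nuclei = array(2, dim = c(30, 5, 5))),
                      c(0.3, 0.3, 0.5))
  cmask <- array(TRUE, dim = c(30, 5, 5))
  expect_true(all(central_mip(cgrid, 5, cmask)$nuclei == 2))
  # over-thick window clips with a warning
  expect_warning(central_mip(cgrid, 100, cmask), "clipped")
})

test_that("projected areas recover a disk and flag empty frames", {
  d <- 101
  xc <- outer(rep(1, d), seq_len(d))
  yc <- outer(seq_len(d), rep(1, d))
  disk <- 1.0 * (((xc - 51)^2 + (yc - 51)^2) <= 20^2)
  a <- projected_area(list(disk), pixel_size_um = 1)
  expect_lt(abs(a - pi * 20^2) / (pi * 20^2), 0.02)
  expect_warning(a0 <- projected_area(list(matrix(0, 10, 10))), "empty")
  expect_identical(a0, 0)
})
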