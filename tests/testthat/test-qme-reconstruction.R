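test_that("phase-to-displacement conversion matches the arithmetic", {
  meta <- acquisition_meta()   # 1300 nm, n = 1.4
  z <- matrix(0, 20, 5)
  expect_true(all(displacement_from_phase(z, meta)$u_z == 0))

  # constant pi: u = 1300 / (4 * 1.4) nm = 232.142857 nm
  ph <- matrix(pi, 20, 5)
  u <- displacement_from_phase(ph, meta)$u_z
  expect_equal(unique(as.vector(u)), 1300 / (4 * 1.4) / 1000)
  expect_equal(unique(as.vector(u)) * 1000, 232.142857, tolerance = 1e-6)

  # round trip at d = 100 nm (unwrapped regime)
  d_um <- 0.1
  phd <- matrix(4 * pi * 1.4 * d_um / 1.3, 20, 5)
  expect_true(all(abs(phd) <= pi))
  expect_equal(unique(as.vector(displacement_from_phase(phd, meta)$u_z)),
               d_um, tolerance = 1e-12)
})

test_that("axial unwrapping survives many wraps", {
  meta <- acquisition_meta()
  # linear displacement ramp spanning several 2-pi wraps
  nz <- 200
  u_true <- seq(0, 2.0, length.out = nz)   # um, ~27 rad of phase
  phase_true <- 4 * pi * 1.4 * u_true / 1.3
  wrapped <- wrap_phase(matrix(phase_true, nz, 3))
  u <- displacement_from_phase(wrapped, meta)$u_z
  expect_equal(u[, 2], u_true, tolerance = 1e-12)
})

test_that("WLS strain is exact for linear displacement", {
  meta <- acquisition_meta()
  nz <- 80
  nx <- 12
  s <- 1e-3
  u <- matrix(rep(s * (seq_len(nz) - 1) * meta$pixel_size[1], nx), nz, nx)
  disp <- structure(list(u_z = u, validity = matrix(TRUE, nz, nx)),
                    class = "displacement_field")
  eps <- strain_wls(disp, meta, fit_window_um = 24, resolution_um = NULL)
  expect_equal(unique(round(as.vector(eps$strain[eps$validity]), 12)), s)
  # edges flagged invalid
  expect_false(any(eps$validity[1:2, ]))
})

test_that("uniform-weight WLS equals an OLS oracle at random pixels", {
  meta <- acquisition_meta()
  nz <- 60
  nx <- 10
  u <- with_seed(5, matrix(rnorm(nz * nx, 0, 0.01), nz, nx))
  disp <- structure(list(u_z = u, validity = matrix(TRUE, nz, nx)),
                    class = "displacement_field")
  half <- round((24 / meta$pixel_size[1] - 1) / 2)
  eps <- strain_wls(disp, meta, fit_window_um = 24, resolution_um = NULL)
  picks <- with_seed(6, cbind(sample((half + 1):(nz - half), 10, TRUE),
                              sample(nx, 10, TRUE)))
  for (i in 1:10) {
    r <- picks[i, 1]
    cidx <- picks[i, 2]
    rows <- (r - half):(r + half)
    depth <- rows * meta$pixel_size[1]
    ols <- unname(coef(lm(u[rows, cidx] ~ depth))[2])
    expect_equal(eps$strain[r, cidx], ols, tolerance = 1e-9)
  }
})

test_that("snr-weighted WLS matches a weighted oracle", {
  nz <- 40
  nx <- 4
  snr <- with_seed(7, matrix(runif(nz * nx, 1, 20), nz, nx))
  meta <- acquisition_meta(snr = snr)
  u <- with_seed(8, matrix(rnorm(nz * nx, 0, 0.01), nz, nx))
  disp <- structure(list(u_z = u, validity = matrix(TRUE, nz, nx)),
                    class = "displacement_field")
  half <- round((24 / meta$pixel_size[1] - 1) / 2)
  eps <- strain_wls(disp, meta, fit_window_um = 24, resolution_um = NULL)
  r <- 20
  cidx <- 3
  rows <- (r - half):(r + half)
  depth <- rows * meta$pixel_size[1]
  wfit <- lm(u[rows, cidx] ~ depth, weights = snr[rows, cidx]^2)
  expect_equal(eps$strain[r, cidx], unname(coef(wfit)[2]),
               tolerance = 1e-9)
})

test_that("two-layer phantom strain is exact away from the interface", {
  cfg <- qme_phantom_config(inclusion = NULL, phase_noise_sd = 0)
  ph <- generate_qme_pair(cfg)
  disp <- displacement_from_phase(ph$phase, ph$meta)
  eps <- strain_wls(disp, ph$meta, fit_window_um = 25, resolution_um = 35)
  dz <- ph$meta$pixel_size[1]
  iface_z <- cfg$layer_thicknesses[1]
  zc <- (seq_len(nrow(eps$strain)) - 0.5) * dz
  # one smoothing support (axial window + truncated kernel) exclusion
  far <- abs(zc - iface_z) > 60
  ok <- far & apply(eps$validity, 1, all)
  rel <- abs(eps$strain / ph$truth_strain - 1)
  expect_lt(max(rel[ok, ]), 1e-6)
})

test_that("layer stress follows the calibration curve", {
  nz <- 50
  nx <- 6
  eps <- structure(list(strain = matrix(0.01, nz, nx),
                        validity = matrix(TRUE, nz, nx),
                        resolution_um = 35), class = "strain_field")
  cal <- linear_layer_calibration(100, layer_band = c(5, 20),
                                  preload_strain = 0)
  sig <- layer_stress(eps, cal)
  expect_equal(sig$stress_kPa, rep(1.0, nx))
  # zero strain, zero preload: zero stress
  eps0 <- structure(list(strain = matrix(0, nz, nx),
                         validity = matrix(TRUE, nz, nx),
                         resolution_um = 35), class = "strain_field")
  expect_equal(layer_stress(eps0, cal)$stress_kPa, rep(0, nx))
})

test_that("tabulated nonlinear curves interpolate like the oracle", {
  strain_tab <- seq(0, 0.2, by = 0.01)
  stress_tab <- 50 * strain_tab + 400 * strain_tab^2
  cal <- layer_calibration(strain_tab, stress_tab, preload_strain = 0,
                           layer_band = c(2, 9))
  probe <- with_seed(9, runif(10, 0.001, 0.19))
  for (s in probe) {
    eps <- structure(list(strain = matrix(s, 10, 1),
                          validity = matrix(TRUE, 10, 1),
                          resolution_um = 35), class = "strain_field")
    expect_equal(layer_stress(eps, cal)$stress_kPa,
                 approx(strain_tab, stress_tab, xout = s)$y,
                 tolerance = 1e-12)
  }
  # out-of-range strain names the offending position
  eps_big <- structure(list(strain = matrix(0.5, 10, 1),
                            validity = matrix(TRUE, 10, 1),
                            resolution_um = 35), class = "strain_field")
  expect_error(layer_stress(eps_big, cal), "outside the calibrated range")
})

test_that("stress is invariant to reparameterising a monotone tabulation", {
  dense <- seq(0, 0.2, length.out = 401)
  coarse <- seq(0, 0.2, by = 0.02)
  make_eps <- function(v) structure(
    list(strain = matrix(v, 12, 2), validity = matrix(TRUE, 12, 2),
         resolution_um = 35), class = "strain_field")
  for (s in c(0.004, 0.01, 0.03)) {
    # a linear curve interpolates identically on any grid
    s1 <- layer_stress(make_eps(s),
                       layer_calibration(dense, 80 * dense,
                                         preload_strain = 0,
                                         layer_band = c(2, 10)))
    s2 <- layer_stress(make_eps(s),
                       layer_calibration(coarse, 80 * coarse,
                                         preload_strain = 0,
                                         layer_band = c(2, 10)))
    expect_equal(s1$stress_kPa, s2$stress_kPa, tolerance = 1e-12)
  }
})

test_that("zero-noise reconstruction inverts the forward model", {
  cfg <- qme_phantom_config(phase_noise_sd = 0)
  ph <- generate_qme_pair(cfg)
  cal <- linear_layer_calibration(cfg$layer_moduli[1],
                                  layer_band = c(ph$layer_band[1] + 6,
                                                 ph$layer_band[2] - 20),
                                  preload_strain = 0)
  el <- reconstruct_elastogram(ph$phase, ph$meta, cal)
  # interfaces: layer-gel plane and the inclusion rim
  dz <- ph$meta$pixel_size[1]
  dx <- ph$meta$pixel_size[2]
  zc <- (seq_len(nrow(el$E)) - 0.5) * dz
  xc <- (seq_len(ncol(el$E)) - 0.5) * dx
  cz <- cfg$layer_thicknesses[1] + cfg$inclusion$center[1]
  rim <- abs(sqrt(outer((zc - cz)^2, (xc - cfg$inclusion$center[2])^2,
                        "+")) - cfg$inclusion$radius)
  plane <- matrix(abs(zc - cfg$layer_thicknesses[1]), nrow(el$E),
                  ncol(el$E))
  core <- pmin(rim, plane) > 60 & el$validity
  rel <- abs(el$E / ph$truth_E - 1)
  expect_lt(max(rel[core]), 1e-3)
})

test_that("reconstructed strain scales with stress, modulus does not", {
  base <- qme_phantom_config(inclusion = NULL, phase_noise_sd = 0)
  scaled <- qme_phantom_config(inclusion = NULL, phase_noise_sd = 0,
                               applied_stress = 2 * base$applied_stress)
  rec <- function(cfg) {
    ph <- generate_qme_pair(cfg)
    cal <- linear_layer_calibration(cfg$layer_moduli[1],
                                    layer_band = c(ph$layer_band[1] + 6,
                                                   ph$layer_band[2] - 20),
                                    preload_strain = 0)
    disp <- displacement_from_phase(ph$phase, ph$meta)
    eps <- strain_wls(disp, ph$meta)
    list(eps = eps, el = build_elastogram(eps, layer_stress(eps, cal)))
  }
  r1 <- rec(base)
  r2 <- rec(scaled)
  ok <- r1$el$validity & r2$el$validity
  expect_equal(r2$eps$strain[ok], 2 * r1$eps$strain[ok], tolerance = 1e-9)
  expect_equal(r2$el$E[ok], r1$el$E[ok], tolerance = 1e-9)
})

test_that("histogram peaks locate delta and mixture modes", {
  d <- matrix(5, 50, 50)
  el <- structure(list(E = d, stress_kPa = rep(1, 50),
                       validity = matrix(TRUE, 50, 50),
                       display_range = c(0, 20)), class = "elastogram")
  pk <- histogram_peaks(el)
  expect_equal(pk$background_peak_kPa, 5, tolerance = 0.01)

  mix <- with_seed(10, matrix(c(rnorm(2000, 3, 0.15),
                                rnorm(500, 8, 0.3)), 50, 50))
  mask <- matrix(c(rep(FALSE, 2000), rep(TRUE, 500)), 50, 50)
  elm <- structure(list(E = mix, stress_kPa = rep(1, 50),
                        validity = matrix(TRUE, 50, 50),
                        display_range = c(0, 20)), class = "elastogram")
  pkm <- histogram_peaks(elm, spheroid_mask = mask)
  bw <- density(mix[!mask])$bw
  expect_lt(abs(pkm$background_peak_kPa - 3), bw + 0.15)
  expect_lt(abs(pkm$spheroid_peak_kPa - 8), density(mix[mask])$bw + 0.3)
  # too few pixels errors out
  tiny <- structure(list(E = matrix(5, 5, 5), stress_kPa = rep(1, 5),
                         validity = matrix(TRUE, 5, 5),
                         display_range = c(0, 20)), class = "elastogram")
  expect_error(histogram_peaks(tiny), "insufficient data")
})

test_that("noisy inclusion phantoms recover both peaks within 10%", {
  # 10 seeds here (scaled down); the acceptance suite runs 20
  peaks <- vapply(1:10, function(s) {
    cfg <- qme_phantom_config(phase_noise_sd = 0.05, seed = s)
    ph <- generate_qme_pair(cfg)
    cal <- linear_layer_calibration(cfg$layer_moduli[1],
                                    layer_band = c(ph$layer_band[1] + 6,
                                                   ph$layer_band[2] - 20),
                                    preload_strain = 0)
    el <- reconstruct_elastogram(ph$phase, ph$meta, cal)
    pk <- histogram_peaks(el, spheroid_mask = ph$truth_E ==
                            cfg$inclusion$E_kPa)
    c(pk$background_peak_kPa, pk$spheroid_peak_kPa)
  }, numeric(2))
  expect_lt(max(abs(peaks[1, ] / 2.9 - 1)), 0.1)
  expect_lt(max(abs(peaks[2, ] / 6.4 - 1)), 0.1)
})

test_that("scan geometry yields the expected lateral pixel size", {
  expect_equal(lateral_pixel_size(2.2, 1000), 2.2)
})
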