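test_that("spheroid phantom truth is voxel-exact and deterministic", {
  cfg <- small_phantom_config(seed = 7, n_nuclei = 10L)
  ph <- generate_spheroid_stack(cfg)
  voxvol <- prod(cfg$voxel_size)

  # brute-force voxel counting on the noiseless masks reproduces truth
  expect_identical(sum(ph$truth$spheroid_mask) * voxvol,
                   ph$truth$spheroid_volume)
  expect_identical(sum(ph$truth$nuclei_labels > 0L) * voxvol,
                   ph$truth$nuclear_volume_total)
  expect_identical(ph$truth$nuclei_count, 10L)
  expect_identical(nrow(ph$truth$nuclei_centroids), 10L)
  expect_gte(ph$truth$spheroid_volume, ph$truth$nuclear_volume_total)

  # same config, same seed: bit-identical stacks
  ph2 <- generate_spheroid_stack(cfg)
  expect_identical(ph$stack, ph2$stack)
  expect_identical(ph$truth$nuclei_centroids, ph2$truth$nuclei_centroids)

  # different seed moves the nuclei
  ph3 <- generate_spheroid_stack(small_phantom_config(seed = 8,
                                                      n_nuclei = 10L))
  expect_false(identical(ph$truth$nuclei_centroids,
                         ph3$truth$nuclei_centroids))
})

test_that("degenerate one-nucleus phantom is exactly one ellipsoid", {
  cfg <- small_phantom_config(seed = 2, n_nuclei = 1L, blur_sigma = 0)
  ph <- generate_spheroid_stack(cfg)
  expect_identical(ph$truth$nuclei_count, 1L)
  # nuclei channel is nonzero exactly on the single ellipsoid mask
  expect_identical(ph$stack$nuclei > 0, ph$truth$nuclei_labels == 1L)
  lab <- spheromech:::label_components(ph$stack$nuclei > 0, 26L)
  expect_identical(max(lab), 1L)
})

test_that("marker channel mean follows the intensity-volume law", {
  cfg <- small_phantom_config(seed = 3, blur_sigma = 0,
                              marker_law = list(amplitude = 2, rate = 2e-4))
  ph <- generate_spheroid_stack(cfg)
  target <- 2 * exp(2e-4 * ph$truth$spheroid_volume)
  expect_equal(ph$truth$marker_mean_intensity, target)
  expect_equal(mean(ph$stack$marker[ph$truth$spheroid_mask]), target,
               tolerance = 1e-10)
})

test_that("phantom refuses stacks too small for the spheroid", {
  expect_error(
    generate_spheroid_stack(small_phantom_config(
      stack_shape = c(10L, 80L, 80L))),
    "does not fit.*z extent")
})

test_that("QME phantom reproduces the layered closed form", {
  cfg <- qme_phantom_config(inclusion = NULL, phase_noise_sd = 0)
  ph <- generate_qme_pair(cfg)
  eps_layer <- cfg$applied_stress / cfg$layer_moduli[1]
  eps_gel <- cfg$applied_stress / cfg$layer_moduli[2]
  band <- ph$layer_band
  expect_equal(unique(as.vector(ph$truth_strain[band[1]:band[2], ])),
               eps_layer)
  expect_equal(unique(as.vector(ph$truth_strain[(band[2] + 1):nrow(ph$truth_strain), ])),
               eps_gel)

  # zero applied stress: identically zero phase
  ph0 <- generate_qme_pair(qme_phantom_config(applied_stress = 0,
                                              phase_noise_sd = 0))
  expect_true(all(ph0$phase == 0))

  # inclusion at twice the gel modulus strains half as much
  phi <- generate_qme_pair(qme_phantom_config(
    inclusion = list(center = c(z = 275, x = 275), radius = 100,
                     E_kPa = 2 * 2.9),
    phase_noise_sd = 0))
  inc <- phi$truth_E == 2 * 2.9
  expect_equal(unique(as.vector(phi$truth_strain[inc])), eps_gel / 2)
})

test_that("QME phantom refuses aliased configurations", {
  expect_error(
    generate_qme_pair(qme_phantom_config(applied_stress = 1,
                                         layer_moduli = c(20, 0.5),
                                         inclusion = NULL)),
    "aliased configuration refused")
})

test_that("AFM curve generator matches the shared contact model", {
  cfg <- afm_curve_config(E_true = 10, force_noise_sd = 0)
  cv <- generate_afm_curve(cfg)
  C <- pyramid_constant(35, 0.5)
  delta <- pmax(0, cv$separation_um - 2)
  expect_equal(cv$force_nN, C * 10 * delta^2)
  expect_true(all(cv$force_nN[cv$separation_um < 2] == 0))

  # vanishing indentation: all forces ~ 0
  cv0 <- generate_afm_curve(afm_curve_config(max_indentation = 1e-9))
  expect_lt(max(cv0$force_nN), 1e-12)

  # doubling E doubles the post-contact force pointwise
  cv2 <- generate_afm_curve(afm_curve_config(E_true = 20,
                                             force_noise_sd = 0))
  expect_equal(cv2$force_nN, 2 * cv$force_nN)
})

test_that("growth series follows the exponential law", {
  s0 <- generate_growth_series(growth_series_config(rate = 0, noise_sd = 0))
  expect_true(all(s0$area_um2 == 150))

  s <- generate_growth_series(growth_series_config(A0 = 100, rate = 0.4,
                                                   noise_sd = 0))
  fit <- lm(log(s$area_um2) ~ s$time_days)
  expect_equal(unname(coef(fit)), c(log(100), 0.4))

  # with 5% noise over 40 points the rate is recovered within 10%
  # in at least 95% of 200 seeds
  times <- seq(0, 10, length.out = 40)
  hit <- vapply(1:200, function(sd) {
    ser <- generate_growth_series(growth_series_config(
      A0 = 100, rate = 0.4, times = times, noise_sd = 0.05, seed = sd))
    fit <- exponential_growth_fit(ser$time_days, ser$area_um2)
    abs(fit$k - 0.4) / 0.4 <= 0.1
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("generators are pure functions of config and seed", {
  g1 <- generate_growth_series(growth_series_config(noise_sd = 0.1, seed = 5))
  g2 <- generate_growth_series(growth_series_config(noise_sd = 0.1, seed = 5))
  expect_identical(g1, g2)
  a1 <- generate_afm_curve(afm_curve_config(force_noise_sd = 0.05, seed = 5))
  a2 <- generate_afm_curve(afm_curve_config(force_noise_sd = 0.05, seed = 5))
  expect_identical(a1, a2)
  q1 <- generate_qme_pair(qme_phantom_config(phase_noise_sd = 0.05, seed = 5))
  q2 <- generate_qme_pair(qme_phantom_config(phase_noise_sd = 0.05, seed = 5))
  expect_identical(q1$phase, q2$phase)
})
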