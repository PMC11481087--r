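#' Default end-to-end run configuration
#'
#' A fully synthetic demonstration cohort: AFM gradient calibration from
#' triplicate force curves at 2 mm intervals, five stiffness bins of
#' spheroid phantoms whose per-cell volume decreases with local stiffness
#' while nuclear volume stays constant and marker intensity follows an
#' exponential law in spheroid volume, growth series per bin, and one
#' inclusion QME phantom. Phantoms are deliberately desk-scale (few cells,
#' coarse voxels) so a full run stays in minutes.
#'
#' @param seed global integer seed; each stage derives its own sub-seed
#'   via [stage_seed()].
#' @param n_per_bin spheroids per stiffness bin.
#' @return A nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, n_per_bin = 10L) {
  cfg <- list(
    seed = as.integer(seed),
    gradient = list(
      positions_mm = c(0, 2, 4, 6, 8),
      true_slope_kPa_per_mm = 1.85,
      true_intercept_kPa = 2.0,
      replicates = 3L,
      force_noise_sd = 0.02,
      contact_point_um = 2,
      max_indentation_um = 0.6,
      tip_half_angle_deg = 35,
      poisson_ratio = 0.5),
    cohort = list(
      n_per_bin = as.integer(n_per_bin),
      n_nuclei_range = c(6L, 8L),
      nuclear_volume_um3 = 30,
      cell_volume_soft_um3 = 700,
      cell_volume_slope_um3_per_kPa = -15,
      volume_noise_sd = 0.10,
      voxel_size_um = c(0.6, 0.6, 0.6),
      blur_sigma_um = 0.6,
      gaussian_sd = 0.1,
      poisson_scale = 100,
      marker_amplitude = 2,
      marker_rate = 5e-4,
      yap_ratio = 0.8,
      min_nucleus_volume_um3 = 10),
    growth = list(
      A0_um2 = 150,
      rate_soft_per_day = 0.55,
      rate_slope_per_kPa = -0.02,
      times_days = 0:10,
      noise_sd = 0.05),
    qme = list(
      E_gel_kPa = 2.9,
      E_inclusion_kPa = 6.4,
      E_layer_kPa = 20,
      inclusion_radius_um = 100,
      applied_stress_kPa = 0.01,
      preload_strain = 0.05,
      phase_noise_sd = 0.05))
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Schema-validates a configuration (a `run_config` list or a YAML file
#' path): unknown keys are rejected and all invariant violations are
#' reported at once.
#'
#' @param config a `run_config` list or path to a YAML file.
#' @return Character vector of violations (length 0 when valid).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))

  known_top <- c("seed", "gradient", "cohort", "growth", "qme")
  extra <- setdiff(names(config), known_top)
  if (length(extra)) say("unknown key(s): %s", paste(extra, collapse = ", "))
  ref <- unclass(default_run_config())
  for (blk in c("gradient", "cohort", "growth", "qme")) {
    if (is.null(config[[blk]])) { say("missing block: %s", blk); next }
    extra <- setdiff(names(config[[blk]]), names(ref[[blk]]))
    if (length(extra))
      say("unknown key(s) in %s: %s", blk, paste(extra, collapse = ", "))
    miss <- setdiff(names(ref[[blk]]), names(config[[blk]]))
    if (length(miss))
      say("missing key(s) in %s: %s", blk, paste(miss, collapse = ", "))
  }
  if (is.null(config$seed) || !is.numeric(config$seed))
    say("seed: required integer")
  g <- config$gradient
  if (!is.null(g)) {
    if (!is.null(g$positions_mm) && length(unique(g$positions_mm)) < 2)
      say("gradient.positions_mm: need >= 2 distinct positions")
    if (!is.null(g$force_noise_sd) && g$force_noise_sd < 0)
      say("gradient.force_noise_sd: must be >= 0")
    if (!is.null(g$true_intercept_kPa) && !is.null(g$true_slope_kPa_per_mm) &&
        !is.null(g$positions_mm)) {
      E <- g$true_intercept_kPa + g$true_slope_kPa_per_mm * g$positions_mm
      if (any(E <= 0))
        say("gradient: map yields non-positive stiffness at some position")
    }
  }
  ch <- config$cohort
  if (!is.null(ch)) {
    for (k in c("nuclear_volume_um3", "cell_volume_soft_um3",
                "poisson_scale", "marker_amplitude", "yap_ratio",
                "min_nucleus_volume_um3"))
      if (!is.null(ch[[k]]) && any(ch[[k]] <= 0))
        say("cohort.%s: must be positive", k)
    if (!is.null(ch$voxel_size_um) &&
        (length(ch$voxel_size_um) != 3 || any(ch$voxel_size_um <= 0)))
      say("cohort.voxel_size_um: need 3 positive values")
    if (!is.null(ch$n_per_bin) && ch$n_per_bin < 1)
      say("cohort.n_per_bin: must be >= 1")
  }
  gr <- config$growth
  if (!is.null(gr)) {
    if (!is.null(gr$A0_um2) && gr$A0_um2 <= 0) say("growth.A0_um2: must be positive")
    if (!is.null(gr$times_days) && any(diff(gr$times_days) <= 0))
      say("growth.times_days: must be strictly increasing")
  }
  q <- config$qme
  if (!is.null(q)) {
    for (k in c("E_gel_kPa", "E_inclusion_kPa", "E_layer_kPa",
                "inclusion_radius_um"))
      if (!is.null(q[[k]]) && any(q[[k]] <= 0))
        say("qme.%s: must be positive", k)
    if (!is.null(q$preload_strain) &&
        (q$preload_strain < 0 || q$preload_strain >= 1))
      say("qme.preload_strain: must be in [0, 1)")
    if (!is.null(q$applied_stress_kPa) && q$applied_stress_kPa < 0)
      say("qme.applied_stress_kPa: must be >= 0")
  }
  v
}

# simulate + segment + quantify one cohort of spheroid phantoms
simulate_cohort <- function(cfg, cal, seed) {
  ch <- cfg$cohort
  positions <- cfg$gradient$positions_mm
  morpho <- list()
  markers <- list()
  counter <- 0L
  mean_n <- mean(ch$n_nuclei_range)
  for (b in seq_along(positions)) {
    E_bin <- stiffness_at(cal, positions[b])
    cv_bin <- ch$cell_volume_soft_um3 +
      ch$cell_volume_slope_um3_per_kPa * (E_bin - stiffness_at(cal, min(positions)))
    if (cv_bin <= ch$nuclear_volume_um3)
      stop("cohort: cell volume at ", signif(E_bin, 3),
           " kPa is not above the nuclear volume", call. = FALSE)
    for (s in seq_len(ch$n_per_bin)) {
      counter <- counter + 1L
      sseed <- stage_seed(seed, counter)
      draws <- with_seed(sseed, list(
        n = sample(seq(ch$n_nuclei_range[1], ch$n_nuclei_range[2]), 1),
        lognoise = rnorm(1, 0, ch$volume_noise_sd)))
      # target volume independent of the drawn count, so count and volume
      # stay uncorrelated across the cohort
      V_target <- mean_n * cv_bin * exp(draws$lognoise)
      pcfg <- spheroid_phantom_config(
        n_nuclei = draws$n,
        nuclear_volume = ch$nuclear_volume_um3,
        cell_volume = V_target / draws$n,
        voxel_size = ch$voxel_size_um,
        blur_sigma = ch$blur_sigma_um,
        noise = list(gaussian_sd = ch$gaussian_sd,
                     poisson_scale = ch$poisson_scale),
        marker_law = list(amplitude = ch$marker_amplitude,
                          rate = ch$marker_rate),
        yap_ratio_true = ch$yap_ratio,
        seed = sseed)
      ph <- generate_spheroid_stack(pcfg)
      grid <- voxel_grid(ph$stack, ch$voxel_size_um)
      mask <- segment_spheroid(grid)
      nuc_f <- prefilter_nuclei_channel(grid, radius = 1L, sigma = 1)
      labs <- segment_nuclei(nuc_f, mask, ch$voxel_size_um,
                             min_sep_um = 0.9 *
                               (3 * ch$nuclear_volume_um3 / (4 * pi))^(1 / 3) * 2,
                             min_volume_um3 = ch$min_nucleus_volume_um3)
      rec <- compute_morphometry(mask, labs, ch$voxel_size_um,
                                 position_mm = positions[b],
                                 stiffness_kPa = E_bin,
                                 spheroid_id = sprintf("sph_%03d", counter))
      morpho[[counter]] <- rec
      markers[[counter]] <- data.frame(
        spheroid_id = rec$spheroid_id,
        marker_name = "marker",
        mean_intensity = mean_marker_intensity(grid$channels$marker, mask,
                                               ch$voxel_size_um),
        nuc_cyto_ratio = yap_nuc_cyto_ratio(grid$channels$marker, labs,
                                            mask, ch$voxel_size_um),
        stiffness_kPa = E_bin,
        spheroid_volume_um3 = rec$spheroid_volume_um3)
    }
  }
  list(morphometry = do.call(rbind, morpho),
       markers = do.call(rbind, markers))
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order — AFM gradient calibration,
#' spheroid cohort simulation + 3D morphometry + marker quantification,
#' growth-series fits, QME phantom reconstruction, and the figure-style
#' report — writing CSV/JSON outputs plus a manifest with input hashes.
#' Rerunning with the same config reproduces byte-identical outputs.
#'
#' @param config a `run_config` (see [default_run_config()]) or YAML path.
#' @param out_dir output directory.
#' @return A list with the calibration, morphometry and marker tables,
#'   growth and QME summaries, the report and the manifest, invisibly.
#' @export
run_full_pipeline <- function(config = default_run_config(),
                              out_dir = tempfile("spheromech_run_")) {
  if (is.character(config)) {
    problems <- validate_run_config(config)
    cfg <- yaml::read_yaml(config)
  } else {
    cfg <- config
    problems <- validate_run_config(unclass(cfg))
  }
  if (length(problems))
    stop("invalid run config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  # stage 1: AFM curves -> gradient calibration
  g <- cfg$gradient
  pts <- list()
  k <- 0L
  for (pos in g$positions_mm) {
    E_true <- g$true_intercept_kPa + g$true_slope_kPa_per_mm * pos
    for (r in seq_len(g$replicates)) {
      k <- k + 1L
      acfg <- afm_curve_config(E_true = E_true,
                               poisson_ratio = g$poisson_ratio,
                               tip_half_angle = g$tip_half_angle_deg,
                               contact_point = g$contact_point_um,
                               max_indentation = g$max_indentation_um,
                               force_noise_sd = g$force_noise_sd,
                               seed = stage_seed(seed, 100000L + k))
      curve <- generate_afm_curve(acfg, position_mm = pos, replicate = r)
      contact <- detect_contact_point(curve)
      fitE <- fit_young_modulus(curve,
                                indenter_model(g$tip_half_angle_deg,
                                               g$poisson_ratio), contact)
      pts[[k]] <- data.frame(position_mm = pos, replicate = r,
                             E_kPa = fitE$E_kPa)
    }
  }
  pts <- do.call(rbind, pts)
  cal <- fit_linear_gradient(pts)
  write_gradient_calibration(cal, file.path(out_dir, "calibration.json"))

  # stage 2: cohort simulation + morphometry + markers
  cohort <- simulate_cohort(cfg, cal, stage_seed(seed, 200000L))
  write.csv(cohort$morphometry, file.path(out_dir, "morphometry.csv"),
            row.names = FALSE)
  write.csv(cohort$markers, file.path(out_dir, "markers.csv"),
            row.names = FALSE)

  # stage 3: growth series per stiffness bin
  gr <- cfg$growth
  growth_rows <- list()
  growth_fits <- list()
  for (b in seq_along(g$positions_mm)) {
    E_bin <- stiffness_at(cal, g$positions_mm[b])
    k_true <- gr$rate_soft_per_day +
      gr$rate_slope_per_kPa * (E_bin - stiffness_at(cal, min(g$positions_mm)))
    series <- generate_growth_series(growth_series_config(
      A0 = gr$A0_um2, rate = k_true, times = gr$times_days,
      noise_sd = gr$noise_sd, seed = stage_seed(seed, 300000L + b)))
    fit <- exponential_growth_fit(series$time_days, series$area_um2)
    growth_rows[[b]] <- cbind(stiffness_kPa = E_bin, series)
    growth_fits[[b]] <- list(stiffness_kPa = E_bin, k_true = k_true,
                             A0 = fit$A0, k = fit$k, r2 = fit$r2)
  }
  write.csv(do.call(rbind, growth_rows), file.path(out_dir, "growth.csv"),
            row.names = FALSE)

  # stage 4: QME phantom + reconstruction
  q <- cfg$qme
  qcfg <- qme_phantom_config(
    layer_moduli = c(E_layer = q$E_layer_kPa, E_gel = q$E_gel_kPa),
    inclusion = list(center = c(z = 275, x = 275),
                     radius = q$inclusion_radius_um,
                     E_kPa = q$E_inclusion_kPa),
    applied_stress = q$applied_stress_kPa,
    preload_strain = q$preload_strain,
    phase_noise_sd = q$phase_noise_sd,
    seed = stage_seed(seed, 400000L))
  ph <- generate_qme_pair(qcfg)
  band <- ph$layer_band
  lcal <- linear_layer_calibration(
    q$E_layer_kPa,
    layer_band = c(band[1] + 6L, band[2] - 20L),
    preload_strain = 0)
  elast <- reconstruct_elastogram(ph$phase, ph$meta, lcal)
  inclusion_mask <- ph$truth_E == q$E_inclusion_kPa
  peaks <- histogram_peaks(elast, spheroid_mask = inclusion_mask)
  qme_summary <- list(background_peak_kPa = peaks$background_peak_kPa,
                      spheroid_peak_kPa = peaks$spheroid_peak_kPa,
                      true_gel_kPa = q$E_gel_kPa,
                      true_inclusion_kPa = q$E_inclusion_kPa)
  jsonlite::write_json(qme_summary, file.path(out_dir, "qme_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # stage 5: report
  report <- assemble_report(cohort$morphometry, cohort$markers,
                            out_dir = file.path(out_dir, "report"))
  jsonlite::write_json(growth_fits, file.path(out_dir, "growth_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("spheromech")),
    seed = seed,
    config = unclass(cfg),
    outputs = lapply(setNames(files, sub(paste0("^", out_dir, "/?"), "",
                                         files)),
                     function(f) digest::digest(file = f, algo = "sha256")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calibration = cal,
                 morphometry = cohort$morphometry,
                 markers = cohort$markers,
                 growth_fits = growth_fits,
                 qme = qme_summary,
                 report = report,
                 manifest = manifest,
                 out_dir = out_dir))
}
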