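## End-to-end drivers for the two headline experiments: the two-contrast
## phantom tissue-independence/FWHM study and the prone-versus-supine
## position comparison on digital subjects.

# Calibrated baseline noise standard deviations for the phantom-scale
# simulation (see the methods vignette): the external:body ratio is fixed so
# interior per-voxel SNR sits at roughly a 5:3 array:body ratio, and the
# global scale is frozen so the baseline two-contrast percent-difference
# FWHM lands at the reference value.
RSNR_BASELINE_SIGMA <- c(ext = 0.00888, body = 0.04172)

#' Compute the paired rSNR maps for a two-contrast phantom dataset
#'
#' Sensitivity maps and the channel noise covariance of each coil are
#' estimated once (from the contrast-A acquisition) and reused for contrast
#' B: both are properties of coil, geometry and receiver chain, not of
#' contrast. Holding them fixed within a pair makes the noiseless contrast
#' cancellation exact and removes the global percent-difference offset that
#' independent finite-sample covariance estimates would induce. In the
#' noiseless limit the configured baseline covariance is used for the noise
#' denominators so SNR stays defined.
#'
#' @param ds output of [tissue_independence_dataset()].
#' @param config the [tissue_independence_config()] used to generate it.
#' @param calib_region sensitivity calibration-region size.
#' @param min_ref_snr reference-SNR validity floor.
#' @return list with `rsnr_a`, `rsnr_b` (`rsnr_volume`s) and the SNR maps.
#' @export
phantom_rsnr_maps <- function(ds, config, calib_region = c(24, 24, 12),
                              min_ref_snr = 2) {
  sens_ext <- estimate_sensitivity_maps(ds$ext_a, calib_region)
  meas_or_config <- function(ks, sigma, rho = 0) {
    nc <- estimate_noise_covariance(ks$noise_block)
    if (all(Mod(nc$psi) == 0)) {
      if (rho > 0) default_noise_covariance(nrow(nc$psi), sigma, rho)
      else noise_covariance(diag(sigma^2, nrow(nc$psi)))
    } else nc
  }
  nc_ext <- meas_or_config(ds$ext_a, config$sigma_ext, config$rho_ext)
  nc_body <- meas_or_config(ds$body_a, config$sigma_body)
  snr_ea <- snr_map(sense_reconstruct(ds$ext_a, sens_ext, nc_ext), provenance = "array")
  snr_eb <- snr_map(sense_reconstruct(ds$ext_b, sens_ext, nc_ext), provenance = "array")
  snr_ba <- body_coil_snr_map(ds$body_a, nc_body)
  snr_bb <- body_coil_snr_map(ds$body_b, nc_body)
  list(
    rsnr_a = compute_rsnr(snr_ea, snr_ba, min_ref_snr),
    rsnr_b = compute_rsnr(snr_eb, snr_bb, min_ref_snr),
    snr_ext = list(a = snr_ea, b = snr_eb),
    snr_body = list(a = snr_ba, b = snr_bb)
  )
}

#' Run the two-contrast phantom FWHM experiment
#'
#' Simulates the paired two-contrast, two-coil phantom acquisitions, builds
#' rSNR maps for each contrast, forms the symmetric percent-difference map
#' over the shared valid volume, and measures its histogram FWHM — under
#' three noise conditions: baseline; both coils' noise variance divided by
#' 10; and only the external array's variance divided by 10. Each condition
#' is repeated over independent seeds.
#'
#' @param config a [tissue_independence_config()].
#' @param seed master seed.
#' @param n_seeds Monte-Carlo repetitions per condition (default 5).
#' @param bin_width FWHM histogram bin width (percent-difference units).
#' @return object of class `phantom_experiment_report`: per condition the
#'   FWHM for each seed, the mean and the spread.
#' @export
run_phantom_experiment <- function(config = tissue_independence_config(),
                                   seed = 1L, n_seeds = 5L, bin_width = 0.5) {
  conditions <- list(
    baseline = c(ext = 1, body = 1),
    both_tenth = c(ext = 0.1, body = 0.1),
    external_tenth = c(ext = 0.1, body = 1)
  )
  out <- list()
  for (cn in names(conditions)) {
    sc <- conditions[[cn]]
    cfg <- config
    cfg$noise_scale_ext <- config$noise_scale_ext * sc[["ext"]]
    cfg$noise_scale_body <- config$noise_scale_body * sc[["body"]]
    fw <- numeric(n_seeds)
    nvals <- integer(n_seeds)
    for (i in seq_len(n_seeds)) {
      ds <- tissue_independence_dataset(cfg, derive_seed(seed, 100L * match(cn, names(conditions)) + i))
      maps <- phantom_rsnr_maps(ds, cfg)
      pd <- percent_difference_map(maps$rsnr_a, maps$rsnr_b)
      fw[i] <- tryCatch(histogram_fwhm(pd, bin_width), error = function(e)
        stop_rsnr("FWHM degenerate under condition '%s' (seed %d): %s",
                  cn, i, conditionMessage(e)))
      nvals[i] <- sum(pd$valid_mask)
    }
    out[[cn]] <- list(fwhm = fw, mean = mean(fw), sd = stats::sd(fw),
                      n_voxels = nvals)
  }
  structure(list(conditions = out, n_seeds = n_seeds, seed = seed,
                 bin_width = bin_width, config = config),
            class = "phantom_experiment_report")
}

#' @export
print.phantom_experiment_report <- function(x, ...) {
  cat("<phantom_experiment_report> percent-difference FWHM\n")
  for (cn in names(x$conditions))
    cat(sprintf("  %-15s %.2f (sd %.2f over %d seeds)\n", cn,
                x$conditions[[cn]]$mean, x$conditions[[cn]]$sd, x$n_seeds))
  invisible(x)
}

#' Default configuration for the prone-versus-supine comparison
#'
#' @param subject_volumes_ml breast-volume targets (mL) of the digital
#'   subjects, spanning the clinical range.
#' @param grid_shape simulation grid (A/P, R/L, S/I); phase-encode dims must
#'   be divisible by the acceleration factors.
#' @param voxel_size_mm voxel size, mm.
#' @param n_channels_supine,n_channels_prone array element counts (supine
#'   conformal surface array; prone lateral paddles).
#' @param element_diameter_mm element diameter, mm.
#' @param sigma_array,sigma_body noise standard deviations.
#' @param accels list of `c(R_si, R_rl)` accelerations.
#' @param n_boot,alpha bootstrap test parameters.
#' @param bin_mm distance-profile bin width.
#' @param min_ref_snr rSNR reference floor.
#' @param calib_region sensitivity calibration region.
#' @return named list of class `position_comparison_config`.
#' @export
position_comparison_config <- function(subject_volumes_ml = c(800, 1400, 2200),
                                       grid_shape = c(64, 48, 40),
                                       voxel_size_mm = c(5, 5, 5),
                                       n_channels_supine = 60L,
                                       n_channels_prone = 16L,
                                       element_diameter_mm = 70,
                                       sigma_array = 0.004,
                                       sigma_body = 0.03,
                                       accels = list(c(1L, 1L), c(2L, 4L)),
                                       n_boot = 10000L,
                                       alpha = 0.01,
                                       bin_mm = 2,
                                       min_ref_snr = 2,
                                       calib_region = c(24, 24, 12)) {
  stopifnot(alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "position_comparison_config")
}

# one position of one subject: simulate, reconstruct, map
simulate_position <- function(subject, config, seed) {
  position <- subject$position_tag
  coil <- if (position == "supine")
    make_coil_array("surface_conformal", subject,
                    config$n_channels_supine, config$element_diameter_mm)
  else
    make_coil_array("side_paddles", subject,
                    config$n_channels_prone, config$element_diameter_mm)
  body <- make_coil_array("body", subject$signal, 1L)
  sens_true <- evaluate_sensitivities(coil, subject$signal)
  psi_arr <- default_noise_covariance(coil$channel_count, config$sigma_array, 0.2)
  psi_body <- noise_covariance(matrix(config$sigma_body^2))
  ks_arr <- simulate_acquisition(subject$signal, sens_true, psi_arr,
                                 seed = derive_seed(seed, 1L),
                                 meta = list(coil = coil$geometry, position = position))
  ks_body <- simulate_acquisition(subject$signal,
                                  evaluate_sensitivities(body, subject$signal),
                                  psi_body, seed = derive_seed(seed, 2L),
                                  meta = list(coil = "body", position = position))
  calib <- pmin(config$calib_region, dim_of(ks_arr))
  sens <- estimate_sensitivity_maps(ks_arr, calib)
  nc_arr <- estimate_noise_covariance(ks_arr$noise_block)
  nc_body <- estimate_noise_covariance(ks_body$noise_block)
  snr_body <- body_coil_snr_map(ks_body, nc_body)
  rsnr <- list()
  for (accel in config$accels) {
    ks <- if (all(accel == 1L)) ks_arr else subsample_kspace(ks_arr, accel)
    recon <- sense_reconstruct(ks, sens, nc_arr, accel)
    snr_arr <- snr_map(recon, provenance = "array")
    key <- paste0("r", accel[1], "x", accel[2])
    rsnr[[key]] <- compute_rsnr(snr_arr, snr_body, config$min_ref_snr)
    rsnr[[key]]$meta$gfactor_median <-
      stats::median(recon$gfactor[recon$valid_mask])
  }
  geometry <- if (position == "supine") coil_model_geometry(coil)
              else prone_coil_geometry(subject$labels)
  distmap <- distance_to_coil_map(subject$labels, geometry)
  list(subject = subject, coil = coil, rsnr = rsnr,
       geometry = geometry, distmap = distmap, snr_body = snr_body)
}

#' Run the prone-versus-supine rSNR comparison end-to-end
#'
#' For each digital-subject preset: generates prone and supine subjects and
#' their coils, simulates array and body-coil acquisitions, computes SNR and
#' rSNR maps at every configured acceleration, runs the bootstrapped
#' percentile-difference tests (3 regions x 5 percentiles per acceleration,
#' supine minus prone), estimates breast volume, and builds distance-
#' from-coil profiles; then fits the supine:prone median-ratio versus
#' breast-volume trend per region across subjects.
#'
#' @param config a [position_comparison_config()].
#' @param seed master seed.
#' @return object of class `comparison_report` with `subjects` (per-subject
#'   results), `tests` (tidy data frame), `ratios`, `trends`,
#'   `distance_profiles`, and provenance.
#' @export
run_position_comparison <- function(config = position_comparison_config(),
                                    seed = 1L) {
  regions <- c("breast", "chest_wall", "axilla")
  subjects <- list()
  tests <- list(); ratios <- list()
  for (i in seq_along(config$subject_volumes_ml)) {
    vol <- config$subject_volumes_ml[i]
    res <- list()
    for (position in c("prone", "supine")) {
      subj <- make_digital_subject(position, vol, config$grid_shape,
                                   config$voxel_size_mm,
                                   seed = derive_seed(seed, 10L * i))
      res[[position]] <- simulate_position(subj, config,
                                           derive_seed(seed, 10L * i +
                                             if (position == "prone") 1L else 2L))
    }
    bv <- breast_volume_ml(res$supine$subject$labels)
    subjects[[i]] <- c(res, list(breast_volume_ml = bv,
                                 breast_volume_prone_ml =
                                   breast_volume_ml(res$prone$subject$labels)))
    tcount <- 0L
    for (accel_key in names(res$supine$rsnr)) {
      for (rg in regions) {
        v_sup <- extract_region_values(res$supine$rsnr[[accel_key]],
                                       res$supine$subject$labels, rg)
        v_pro <- extract_region_values(res$prone$rsnr[[accel_key]],
                                       res$prone$subject$labels, rg)
        ratios[[length(ratios) + 1L]] <- data.frame(
          subject = i, accel = accel_key, region = rg, volume_ml = bv,
          ratio = stats::median(v_sup) / stats::median(v_pro)
        )
        for (pp in RSNR_PERCENTILES) {
          tcount <- tcount + 1L
          tst <- bootstrap_percentile_test(
            v_sup, v_pro, pp, config$n_boot, config$alpha,
            seed = derive_seed(seed, 1000L * i + tcount))
          tests[[length(tests) + 1L]] <- data.frame(
            subject = i, accel = accel_key, region = rg, percentile = pp,
            supine = stats::quantile(v_sup, pp / 100, names = FALSE),
            prone = stats::quantile(v_pro, pp / 100, names = FALSE),
            diff = tst$diff, p_value = tst$p_value,
            significant = tst$significant, direction = tst$direction
          )
        }
      }
    }
  }
  tests <- do.call(rbind, tests)
  ratios <- do.call(rbind, ratios)
  trends <- list()
  if (length(config$subject_volumes_ml) >= 2) {
    for (accel_key in unique(ratios$accel)) for (rg in regions) {
      pts <- ratios[ratios$accel == accel_key & ratios$region == rg, ]
      trends[[paste(accel_key, rg, sep = ".")]] <-
        ratio_vs_volume_trend(pts, rg)
    }
  }
  profiles <- lapply(subjects, function(s) {
    lapply(s[c("prone", "supine")], function(ps)
      rsnr_vs_distance(ps$rsnr[[1]], ps$distmap, ps$subject$labels,
                       config$bin_mm))
  })
  structure(list(
    subjects = subjects, tests = tests, ratios = ratios, trends = trends,
    distance_profiles = profiles, seed = seed, config = config
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d subjects, %d tests (%d significant)\n",
              length(x$subjects), nrow(x$tests), sum(x$tests$significant)))
  agg <- stats::aggregate(ratio ~ region + accel, data = x$ratios, FUN = stats::median)
  for (r in seq_len(nrow(agg)))
    cat(sprintf("  median supine:prone ratio, %s @ %s: %.2f\n",
                agg$region[r], agg$accel[r], agg$ratio[r]))
  invisible(x)
}

#' Serialize a report to JSON (+ tidy CSVs for table-like parts)
#'
#' @param report a `phantom_experiment_report` or `comparison_report`.
#' @param out_dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (inherits(report, "phantom_experiment_report")) {
    p <- file.path(out_dir, "phantom_fwhm.json")
    jsonlite::write_json(list(
      seed = report$seed, n_seeds = report$n_seeds,
      bin_width = report$bin_width,
      conditions = lapply(report$conditions, function(cc)
        list(fwhm = cc$fwhm, mean = cc$mean, sd = cc$sd))
    ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- p
  } else if (inherits(report, "comparison_report")) {
    pt <- file.path(out_dir, "percentile_tests.csv")
    utils::write.csv(report$tests, pt, row.names = FALSE)
    pr <- file.path(out_dir, "median_ratios.csv")
    utils::write.csv(report$ratios, pr, row.names = FALSE)
    pj <- file.path(out_dir, "comparison_summary.json")
    jsonlite::write_json(list(
      seed = report$seed,
      n_subjects = length(report$subjects),
      breast_volumes_ml = vapply(report$subjects, `[[`, numeric(1), "breast_volume_ml"),
      trends = lapply(report$trends, function(t)
        list(region = t$region, slope = t$slope, intercept = t$intercept,
             n_points = t$n_points, n_above_reference = t$n_above_reference)),
      n_significant = sum(report$tests$significant)
    ), pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pd <- file.path(out_dir, "distance_profiles.csv")
    rows <- list()
    for (i in seq_along(report$distance_profiles))
      for (position in names(report$distance_profiles[[i]])) {
        pf <- report$distance_profiles[[i]][[position]]$profile
        pf$subject <- i; pf$position <- position
        rows[[length(rows) + 1L]] <- pf
      }
    utils::write.csv(do.call(rbind, rows), pd, row.names = FALSE)
    paths <- c(pt, pr, pj, pd)
  } else stop_rsnr("unknown report type")
  invisible(paths)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of
#' [tissue_independence_config()] (under `phantom:`) and
#' [position_comparison_config()] (under `comparison:`).
#'
#' @param path YAML file path.
#' @return list with `phantom` and/or `comparison` config objects.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$phantom))
    out$phantom <- do.call(tissue_independence_config, y$phantom)
  if (!is.null(y$comparison)) {
    if (!is.null(y$comparison$accels))
      y$comparison$accels <- lapply(y$comparison$accels, as.integer)
    out$comparison <- do.call(position_comparison_config, y$comparison)
  }
  out
}
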