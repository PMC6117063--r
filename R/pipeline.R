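#' Run the full generate-analyze-report pipeline
#'
#' Generates a synthetic retina data set for the configured stages and
#' scenario, then runs every analysis stage: derived cell metrics and
#' log-rate balance decomposition, exponential growth fit, cell-cycle
#' statistics from lineage tracks, the mean-field
#' division/differentiation model, apical mitotic density mapping and
#' occupancy, the mitotic-frustum trap test, apicobasal profile zones and
#' concordance, cortical ratios, and the tension-schedule tissue
#' trajectories. Deterministic given (config, scenario, seed).
#'
#' @param config a [load_config()] object (default: packaged reference
#'   configuration).
#' @param scen a [scenario()].
#' @param seed master seed (default from config).
#' @param out_dir optional directory; when given, module CSVs and
#'   `report.json` are written there.
#' @return A list of class `analysis_report`.
#' @export
run_pipeline <- function(config = load_config(), scen = scenario("control"),
                         seed = config$seed, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"), inherits(scen, "pse_scenario"))
  calib <- config$calibration
  tab <- generate_stage_table(config, scen, seed = seed)

  metrics <- derive_cell_metrics(tab, config$thickness_correction,
                                 config$cmz_correction_factor)
  fit <- exponential_growth_fit(metrics$stage_hpf, metrics$mean_tissue_volume)
  rates <- log_rate_decomposition(data.frame(
    stage_hpf = metrics$stage_hpf, tissue_volume = metrics$mean_tissue_volume,
    n_cells = metrics$mean_cells, cell_volume = metrics$mean_cell_volume,
    tissue_area = metrics$mean_tissue_area,
    tissue_height = metrics$corrected_thickness))

  # cell-cycle statistics from tracks generated at each calibrated stage
  tracks <- unlist(lapply(seq_len(nrow(calib)), function(i)
    generate_cell_cycle_tracks(40, calib[i, ],
                               seed = child_seed(seed, paste0("trk", i)))),
    recursive = FALSE)
  cyc <- cycle_lengths(tracks, bin_centers = config$stages)

  model <- simulate_growth_model(growth_model_params(),
                                 t_grid = seq(20, 48, by = 1))

  # apical surface statistics per stage
  heat <- lapply(seq_len(nrow(calib)), function(i) {
    cal <- calib[i, ]
    n <- max(20L, round(cal$mean_cells * cal$mitotic_index))
    radius <- sqrt(cal$mean_tissue_volume / cal$mean_thickness / (2 * pi) * 2)
    pts <- generate_mitotic_coordinates(
      n, cap = list(center = c(0, 0, 0), radius = radius, theta_max = pi / 2),
      density_mode = "uniform", seed = child_seed(seed, paste0("xyz", i)))
    sf <- fit_sphere(pts)
    prj <- project_equal_area(pts, sf)
    hm <- density_heatmap(prj, bins = config$heatmap_bins)
    unif <- annulus_uniformity_test(prj, sf, pi / 2,
                                    n_annuli = max(2, min(10, floor(n / 5))))
    list(stage_hpf = cal$stage_hpf, heatmap = hm,
         uniformity_p = unif$p.value)
  })

  occ <- vapply(tab$stages, function(stage) {
    rows <- Filter(function(m) round(m$stage_hpf, 1) == stage, tab$rows)
    mean(vapply(rows, function(m)
      apical_occupancy(m$mitotic_diameters, m$n_mitotic, m$apical_area),
      numeric(1)))
  }, numeric(1))

  cyc_for_trap <- data.frame(stage_hpf = calib$stage_hpf,
                             mean_cycle = calib$cell_cycle_mean,
                             mean_mitosis = calib$mitosis_duration)
  trap <- trap_by_stage(tab, cyc_for_trap, config$thickness_correction,
                        config$cmz_correction_factor)

  zones <- do.call(rbind, lapply(config$stages, function(stage) {
    pr <- generate_intensity_profiles(stage, scen, n_profiles = 9,
                                      seed = child_seed(seed, paste0("pro", stage)),
                                      calibration = calib)
    avg_a <- average_profiles(pr$actin)
    avg_n <- average_profiles(pr$nuclear)
    z <- detect_basal_zone(avg_a)
    cc <- exclusion_zone_concordance(avg_a, avg_n)
    data.frame(stage_hpf = stage, extent_fraction = z$extent_fraction,
               absent = z$absent, concordance = cc$correlation)
  }))

  ratios <- do.call(rbind, lapply(config$stages, function(stage) {
    rp <- generate_region_profiles(stage, scen, n_samples = 5,
                                   seed = child_seed(seed, paste0("reg", stage)))
    r <- vapply(rp, function(s)
      cortical_ratios(s$apical, s$basal, s$lateral)$basal_to_lateral,
      numeric(1))
    data.frame(stage_hpf = stage, basal_to_lateral = mean(r))
  }))

  traj <- scenario_trajectories(times = seq(20, 48, by = 0.5),
                                V0 = calib$mean_tissue_volume[1],
                                growth_rate = calib$tissue_growth_rate[1],
                                t_transition = config$transition_hpf,
                                ramp_hours = config$ramp_hours)
  mech <- traj[[if (scen$name == "hdac1") "hdac1" else "control"]]
  drift <- aspect_drift(mech)

  report <- structure(list(
    schema_version = "1.0",
    provenance = list(seed = seed, scenario = scen$name,
                      stages = config$stages,
                      package_version = as.character(utils::packageVersion("psegrowth"))),
    metrics = metrics,
    growth_fit = list(rate = fit$rate, rate_se = fit$rate_se,
                      doubling_time = fit$doubling_time,
                      fold_change = fit$fold_change),
    log_rates = as.data.frame(rates),
    cycle_stats = cyc,
    growth_model = model,
    occupancy = data.frame(stage_hpf = tab$stages, occupancy = occ),
    heatmap_uniformity = data.frame(
      stage_hpf = vapply(heat, `[[`, numeric(1), "stage_hpf"),
      p_value = vapply(heat, `[[`, numeric(1), "uniformity_p")),
    trap = trap,
    zones = zones,
    cortical = ratios,
    mechanics = list(trajectory = as.data.frame(mech),
                     aspect_drift = drift,
                     aspect_constant = drift < 0.15)),
    class = "analysis_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage_table(tab, file.path(out_dir, "stage_table.csv"))
    utils::write.csv(metrics, file.path(out_dir, "derived_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(rates), file.path(out_dir, "log_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(cyc, file.path(out_dir, "cellcycle_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(model, file.path(out_dir, "growth_model_trajectory.csv"),
                     row.names = FALSE)
    utils::write.csv(trap, file.path(out_dir, "trap_report.csv"),
                     row.names = FALSE)
    utils::write.csv(zones, file.path(out_dir, "zones.csv"), row.names = FALSE)
    utils::write.csv(ratios, file.path(out_dir, "ratios.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(mech), file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE)
    json <- report
    json$heatmaps <- NULL
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", x$provenance$scenario, "| seed",
      x$provenance$seed, "|", length(x$provenance$stages), "stages\n")
  cat(sprintf("  volume growth rate %.4f/h (doubling %.1f h)\n",
              x$growth_fit$rate, x$growth_fit$doubling_time))
  cat(sprintf("  max apical occupancy %.1f%% | trap at any stage: %s\n",
              100 * max(x$occupancy$occupancy), any(x$trap$trap)))
  cat(sprintf("  aspect drift %.1f%% (%s)\n", 100 * x$mechanics$aspect_drift,
              if (x$mechanics$aspect_constant) "constant" else "non-constant"))
  invisible(x)
}

#' Compare two analysis reports
#'
#' Walks the shared numeric quantities of two reports (same schema
#' version) and reports per-quantity differences; per-stage vectors get a
#' rank-sum test where both reports carry per-stage values.
#'
#' @param report_a,report_b `analysis_report` objects.
#' @return data.frame with `quantity`, `value_a`, `value_b`, `difference`.
#' @export
compare_scenarios <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "analysis_report"),
            inherits(report_b, "analysis_report"))
  if (!identical(report_a$schema_version, report_b$schema_version))
    stop("report schema versions differ")
  rows <- list(
    c("growth_rate", report_a$growth_fit$rate, report_b$growth_fit$rate),
    c("doubling_time", report_a$growth_fit$doubling_time,
      report_b$growth_fit$doubling_time),
    c("max_occupancy", max(report_a$occupancy$occupancy),
      max(report_b$occupancy$occupancy)),
    c("mean_basal_to_lateral", mean(report_a$cortical$basal_to_lateral),
      mean(report_b$cortical$basal_to_lateral)),
    c("final_zone_extent",
      utils::tail(report_a$zones$extent_fraction, 1),
      utils::tail(report_b$zones$extent_fraction, 1)),
    c("aspect_drift", report_a$mechanics$aspect_drift,
      report_b$mechanics$aspect_drift))
  out <- data.frame(quantity = vapply(rows, `[[`, character(1), 1),
                    value_a = as.numeric(vapply(rows, `[[`, character(1), 2)),
                    value_b = as.numeric(vapply(rows, `[[`, character(1), 3)))
  out$difference <- out$value_b - out$value_a
  # trend comparison of the cortical ratio series
  a <- report_a$cortical$basal_to_lateral
  b <- report_b$cortical$basal_to_lateral
  if (length(a) == length(b) && length(a) >= 3)
    attr(out, "cortical_trend_p") <-
      stats::wilcox.test(a, b, exact = FALSE)$p.value
  out
}
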