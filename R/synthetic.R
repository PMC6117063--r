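#' Generate a synthetic stage table
#'
#' Draws per-embryo morphometric measurements around the calibrated stage
#' means: tissue volume is multiplicative lognormal (mean-preserving);
#' thickness samples (5 positions) vary around the stage mean; cell counts
#' are lognormal around the calibrated trajectory with Poisson sampling on
#' top; mitotic counts are Binomial(n_cells, mitotic index); mitotic
#' diameters are truncated-normal around the calibrated mean. In the
#' `hdac1` scenario thickness samples are capped at 55 um and the actin
#' calibration is frozen at its 30-hpf state (the latter affects
#' [generate_intensity_profiles()]).
#'
#' @param config a [load_config()] object (its `calibration` and `stages`
#'   are used).
#' @param scen a [scenario()] object.
#' @param n_embryos embryos per stage.
#' @param seed integer seed; output is bit-stable given
#'   (config, scenario, seed).
#' @param n_diameters mitotic diameters measured per retina (default 20).
#' @return A [stage_table()].
#' @export
generate_stage_table <- function(config, scen = scenario("control"),
                                 n_embryos = config$n_embryos, seed = config$seed,
                                 n_diameters = 20) {
  stopifnot(inherits(config, "pipeline_config"), inherits(scen, "pse_scenario"))
  set.seed(child_seed(seed, paste0("stage_table/", scen$name)))
  rows <- list()
  for (stage in config$stages) {
    cal <- scenario_calibration(config$calibration, stage, scen)
    for (e in seq_len(n_embryos)) {
      # mean-preserving lognormal multiplicative noise
      lnoise <- function(cv) if (cv <= 0) 1 else
        exp(stats::rnorm(1, -log(1 + cv^2) / 2, sqrt(log(1 + cv^2))))
      V <- cal$mean_tissue_volume * lnoise(cal$volume_cv)
      th <- cal$mean_thickness *
        (1 + stats::rnorm(5, 0, cal$thickness_cv))
      th <- pmin(pmax(th, 1e-3), scen$thickness_cap)
      n_mean <- cal$mean_cells * lnoise(cal$cells_cv)
      if (cal$cells_cv <= 0) {           # zero-noise limit: fully deterministic
        n_cells <- round(n_mean)
        n_mit <- round(n_cells * cal$mitotic_index)
      } else {
        n_cells <- stats::rpois(1, n_mean)
        n_mit <- stats::rbinom(1, n_cells, cal$mitotic_index)
      }
      d <- cal$mean_mitotic_diameter *
        (1 + stats::rnorm(n_diameters, 0, cal$diameter_cv))
      d <- pmax(d, 0.1 * cal$mean_mitotic_diameter)
      # area split: mean cross-sectional area V/h, apical:basal ratio fixed
      hbar <- mean(th)
      abar <- V / hbar
      rr <- cal$apical_to_basal_area_ratio
      A_ap <- abar * 2 * rr / (1 + rr)
      A_ba <- abar * 2 / (1 + rr)
      nz <- cal$nuclear_zone_height * (1 + stats::rnorm(1, 0, cal$nuclear_zone_cv))
      na <- cal$nuclear_long_axis * (1 + stats::rnorm(1, 0, cal$nuclear_axis_cv))
      rows[[length(rows) + 1L]] <- stage_measurement(
        embryo_id = sprintf("%s_s%g_e%02d", scen$name, stage, e),
        stage_hpf = stage, tissue_volume = V,
        apical_area = A_ap, total_surface_area = A_ap + A_ba,
        thickness_samples = th, n_cells = n_cells, n_mitotic = n_mit,
        mitotic_diameters = d, nuclear_zone_height = max(nz, 1e-3),
        nuclear_long_axis = max(na, 1e-3))
    }
  }
  stage_table(rows)
}

#' Generate mitotic event coordinates on a spherical cap
#'
#' The apical surface is modelled as a spherical cap (center, radius,
#' maximum colatitude measured from the cap pole). `uniform` mode samples
#' uniformly per unit cap area by inverting the closed-form colatitude CDF
#' `(1 - cos(theta)) / (1 - cos(theta_max))`; `gradient` mode imposes an
#' azimuthal density wave `1 + amplitude * cos(phi - phase)` (emulating a
#' naso-temporal differentiation wave) by rejection sampling.
#'
#' @param n number of events.
#' @param cap list with `center` (numeric 3), `radius` (um), `theta_max`
#'   (radians, in (0, pi]), and optionally `pole` (unit 3-vector, default
#'   +z).
#' @param density_mode `"uniform"` or `"gradient"`.
#' @param seed integer seed.
#' @param wave_amplitude azimuthal wave amplitude in [0, 1) for gradient
#'   mode.
#' @param wave_phase azimuth of peak density (radians).
#' @return Object of class `mitotic_points`: list with `points` (n x 3
#'   matrix, um), and the generating `cap`.
#' @export
generate_mitotic_coordinates <- function(n, cap = list(center = c(0, 0, 0),
                                                       radius = 100,
                                                       theta_max = pi / 2),
                                         density_mode = c("uniform", "gradient"),
                                         seed = 1, wave_amplitude = 0.8,
                                         wave_phase = 0) {
  density_mode <- match.arg(density_mode)
  stopifnot(n >= 0, cap$radius > 0, cap$theta_max > 0, cap$theta_max <= pi)
  set.seed(child_seed(seed, "mitotic_xyz"))
  if (n == 0) {
    return(structure(list(points = matrix(numeric(0), 0, 3,
                                          dimnames = list(NULL, c("x", "y", "z"))),
                          cap = cap), class = "mitotic_points"))
  }
  u <- stats::runif(n)
  costh <- 1 - u * (1 - cos(cap$theta_max))
  theta <- acos(costh)
  if (density_mode == "uniform") {
    phi <- stats::runif(n, 0, 2 * pi)
  } else {
    a <- wave_amplitude
    stopifnot(a >= 0, a < 1)
    phi <- numeric(n); i <- 1L
    while (i <= n) {
      p <- stats::runif(1, 0, 2 * pi)
      if (stats::runif(1) < (1 + a * cos(p - wave_phase)) / (1 + a)) {
        phi[i] <- p; i <- i + 1L
      }
    }
  }
  pole <- cap$pole %||% c(0, 0, 1)
  pole <- pole / sqrt(sum(pole^2))
  # orthonormal frame around the pole
  ref <- if (abs(pole[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * pole) * pole; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(pole[2] * e1[3] - pole[3] * e1[2],
          pole[3] * e1[1] - pole[1] * e1[3],
          pole[1] * e1[2] - pole[2] * e1[1])
  st <- sin(theta)
  pts <- cap$radius * (outer(st * cos(phi), e1) + outer(st * sin(phi), e2) +
                         outer(costh, pole))
  pts <- sweep(pts, 2, cap$center, "+")
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, cap = cap), class = "mitotic_points")
}

#' Generate lineage tracks with gamma-distributed cell-cycle lengths
#'
#' Each track records mitotic rounding and chromosome-segregation events for
#' consecutive divisions. Cycle lengths (segregation to segregation) are
#' gamma-distributed with the calibrated stage mean and CV; each mitosis
#' contributes a rounding event `mitosis_duration` before its segregation.
#' Cycle midpoints are placed within +/- 3 h of the calibration stage,
#' matching the stage-binning convention of the track-based estimator.
#'
#' @param n_tracks number of tracks.
#' @param calibration one calibration row (see [default_calibration()]).
#' @param seed integer seed.
#' @param cycles_per_track divisions recorded per track (default 2, i.e. up
#'   to 3 segregations).
#' @return List of class `lineage_tracks`; each element has `track_id` and
#'   `events` (data.frame `event`, `time_hpf`, time-ordered).
#' @export
generate_cell_cycle_tracks <- function(n_tracks, calibration, seed = 1,
                                       cycles_per_track = 2) {
  stopifnot(nrow(calibration) == 1,
            calibration$cell_cycle_mean > calibration$mitosis_duration)
  set.seed(child_seed(seed, "tracks"))
  mu <- calibration$cell_cycle_mean
  cv <- calibration$cell_cycle_cv
  tm <- calibration$mitosis_duration
  stage <- calibration$stage_hpf
  tracks <- lapply(seq_len(n_tracks), function(i) {
    L1 <- rgamma_cv(1, mu, cv)
    mid <- stats::runif(1, stage - 3, stage + 3)
    s <- mid - L1 / 2                      # first recorded segregation
    seg <- s
    for (k in seq_len(cycles_per_track)) {
      L <- if (k == 1) L1 else rgamma_cv(1, mu, cv)
      seg <- c(seg, seg[length(seg)] + L)
    }
    ev <- rbind(data.frame(event = "rounding", time_hpf = seg - tm),
                data.frame(event = "segregation", time_hpf = seg))
    ev <- ev[order(ev$time_hpf), ]
    rownames(ev) <- NULL
    list(track_id = sprintf("track_%04d", i), events = ev)
  })
  structure(tracks, class = "lineage_tracks")
}

# gamma draws parameterized by mean and CV; cv = 0 degenerates to the mean
rgamma_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate apicobasal intensity profile pairs (actin, nuclear)
#'
#' Emulates normalized tissue-wide intensity distributions along the
#' apicobasal axis (0 = apical surface, 1 = basal surface) on a 100-point
#' grid. The actin channel is a lateral baseline plus an apical cortical
#' peak and a basal plateau occupying the calibrated basal fraction of the
#' axis; the nuclear channel is an occupancy profile that falls where the
#' actin plateau rises (the basal nuclear exclusion zone). Scenario
#' `hdac1` freezes the basal extent at its 30-hpf value; `rockout` removes
#' the plateau and lets nuclei occupy the entire axis.
#'
#' @param stage stage (hpf) with a calibration row.
#' @param scen a [scenario()].
#' @param n_profiles number of embryo profiles per channel.
#' @param seed integer seed.
#' @param calibration calibration table (default [default_calibration()]).
#' @param noise_sd Gaussian noise SD; `NULL` uses the calibrated value.
#' @return List with elements `actin` and `nuclear`, each a list of
#'   `apicobasal_profile` objects (see [normalize_profile()]).
#' @export
generate_intensity_profiles <- function(stage, scen = scenario("control"),
                                        n_profiles = 9, seed = 1,
                                        calibration = default_calibration(),
                                        noise_sd = NULL) {
  cal <- scenario_calibration(calibration, stage, scen)
  sd <- noise_sd %||% cal$actin_noise_sd
  set.seed(child_seed(seed, paste0("profiles/", scen$name, "/", stage)))
  x <- seq(0, 1, length.out = 100L)
  ext <- cal$actin_basal_extent_fraction
  b <- 1 - ext
  actin_true <- cal$actin_baseline +
    cal$actin_apical_amp * exp(-(x / 0.04)^2) +
    if (ext > 0) cal$actin_plateau_amp * stats::plogis((x - b) / 0.004) else 0
  nuc_b <- if (scen$name == "rockout" || ext <= 0) 1.01 else b
  nuclear_true <- 0.15 + 0.75 * stats::plogis((nuc_b - x) / 0.004) *
    (1 - 0.6 * exp(-(x / 0.03)^2))        # nuclei excluded basally and sparse at the apical cortex
  mk <- function(truth, channel) lapply(seq_len(n_profiles), function(i) {
    y <- truth + stats::rnorm(length(x), 0, sd)
    normalize_profile(x, y, channel = channel, stage_hpf = stage,
                      embryo_id = sprintf("%s_p%02d", scen$name, i))
  })
  list(actin = mk(actin_true, "actin"), nuclear = mk(nuclear_true, "nuclear"))
}

#' Generate cortical-strip intensity profiles for signal-ratio analysis
#'
#' Emulates intensity traces along manually outlined apical, basal and
#' lateral tissue strips. Each trace is a baseline with cortical peaks
#' (spaced roughly one cell diameter apart) whose height is
#' region-specific. In the control calibration the basal and apical peak
#' heights rise relative to lateral between 30 and 42 hpf (actin
#' redistribution); in the `hdac1` scenario the ratios stay flat.
#'
#' @param stage stage (hpf).
#' @param scen a [scenario()].
#' @param n_samples embryos.
#' @param seed integer seed.
#' @param len points per trace.
#' @return List of `n_samples` lists with numeric traces `apical`, `basal`,
#'   `lateral`.
#' @export
generate_region_profiles <- function(stage, scen = scenario("control"),
                                     n_samples = 5, seed = 1, len = 240L) {
  set.seed(child_seed(seed, paste0("regions/", scen$name, "/", stage)))
  # redistribution schedule: basal/apical cortical amplitude relative to lateral
  sched <- function(s) 1.1 + 1.1 * stats::plogis((s - 35.5) / 2.5)
  amp_rel <- if (scen$name == "hdac1") sched(30) else sched(stage)
  lat_amp <- 0.5
  trace <- function(amp) {
    y <- rep(0.2, len)
    centers <- seq(8, len - 8, by = 16) + round(stats::runif(1, -3, 3))
    for (cc in centers) {
      idx <- seq_len(len)
      y <- y + amp * exp(-((idx - cc) / 2.5)^2) * stats::runif(1, 0.85, 1.15)
    }
    y + stats::rnorm(len, 0, 0.02)
  }
  lapply(seq_len(n_samples), function(i)
    list(apical = trace(lat_amp * amp_rel),
         basal = trace(lat_amp * amp_rel),
         lateral = trace(lat_amp)))
}

#' Generate in-plane division angles
#'
#' von Mises draws; concentration 0 gives the circular uniform
#' distribution (no preferred division orientation).
#'
#' @param n number of angles.
#' @param concentration von Mises concentration (>= 0).
#' @param seed integer seed.
#' @param mean_direction mean direction (radians).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
generate_division_angles <- function(n, concentration = 0, seed = 1,
                                     mean_direction = 0) {
  stopifnot(concentration >= 0)
  set.seed(child_seed(seed, "angles"))
  rvonmises(n, mean_direction, concentration)
}
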