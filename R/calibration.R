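#' Packaged reference calibration of the synthetic retina generator
#'
#' One row per developmental stage (hpf), giving the stage means and noise
#' levels that the generators draw from. The calibration transcribes the
#' headline morphometric anchors of zebrafish retinal PSE growth between
#' 20 and 48 hpf:
#'
#' * tissue volume grows exponentially at 0.055/h from a 20-hpf volume chosen
#'   so that volume per cell at 20 hpf is 441 um^3;
#' * total cell number grows exponentially through 2,177 cells at 20 hpf and
#'   18,000 at 48 hpf (8-fold increase);
#' * mean interphase cell volume is derived as tissue volume / cell number,
#'   so the three series satisfy the balance identity V = N * v exactly at
#'   the level of stage means (441 -> 249 um^3);
#' * tissue thickness spans the 46-63 um band with 55 um at 30 hpf;
#' * progenitor cell cycles shorten from 7.3 h (30 hpf) to 5.3 h (42 hpf)
#'   with decreasing coefficient of variation; mitosis lasts 0.42 h at all
#'   stages;
#' * the basolateral actin accumulation occupies 26%, 20% and 8% of the
#'   apicobasal axis at 30, 36 and 42 hpf;
#' * the nuclear zone height / nuclear long axis quotient (nuclear stacking)
#'   rises from 2.8 at 36 hpf to 5.5 at 42 hpf.
#'
#' Mitotic diameters are back-computed from the interphase cell volume via
#' the sphere-volume relation with the 10% mitotic inflation correction, so
#' the diameter-based volume estimator recovers the calibrated volume.
#'
#' @param stages numeric vector of stages (hpf). Default: the six reference
#'   stages 20, 24, 30, 36, 42, 48.
#' @return data.frame with one row per stage and the calibration columns
#'   documented above.
#' @export
default_calibration <- function(stages = c(20, 24, 30, 36, 42, 48)) {
  stopifnot(is.numeric(stages), !is.unsorted(stages, strictly = TRUE))
  t0 <- 20
  g <- 0.055                       # tissue volume growth rate, 1/h
  n0 <- 2177                       # cells at 20 hpf
  n48 <- 18000                     # cells at 48 hpf
  rn <- log(n48 / n0) / 28         # cell-number growth rate, 1/h
  v0_cell <- 441                   # um^3 per cell at 20 hpf
  V0 <- n0 * v0_cell

  V <- V0 * exp(g * (stages - t0))
  N <- n0 * exp(rn * (stages - t0))
  v_cell <- V / N

  # interpolators over the reference grid for stages off the default list
  ref <- c(20, 24, 30, 36, 42, 48)
  ip <- function(y) stats::approx(ref, y, xout = stages, rule = 2)$y

  data.frame(
    stage_hpf = stages,
    mean_tissue_volume = V,
    volume_cv = 0.12,
    tissue_growth_rate = g,
    mean_thickness = ip(c(46, 50, 55, 56, 61, 63)),
    thickness_cv = 0.05,
    apical_to_basal_area_ratio = 1.3,
    mean_cells = N,
    cells_cv = 0.10,
    mitotic_index = ip(c(0.012, 0.010, 0.013, 0.015, 0.016, 0.010)),
    mean_interphase_volume = v_cell,
    mean_mitotic_diameter = (v_cell / (0.9 * pi / 6))^(1 / 3),
    diameter_cv = 0.06,
    cell_cycle_mean = ip(c(8.0, 7.6, 7.3, 6.3, 5.3, 5.5)),
    cell_cycle_cv = ip(c(0.28, 0.25, 0.22, 0.16, 0.12, 0.12)),
    mitosis_duration = 0.42,
    actin_basal_extent_fraction = ip(c(0.28, 0.27, 0.26, 0.20, 0.08, 0.05)),
    actin_baseline = 0.25,
    actin_apical_amp = 0.9,
    actin_plateau_amp = 0.45,
    actin_noise_sd = 0.04,
    nuclear_zone_height = 8 * ip(c(2.5, 2.6, 2.7, 2.8, 5.5, 7.2)),
    nuclear_zone_cv = 0.06,
    nuclear_long_axis = 8,
    nuclear_axis_cv = 0.05,
    row.names = NULL
  )
}

#' Reference endpoint cell counts
#'
#' The transcribed measured total cell counts at the first and last
#' reference stage (about 2,200 at 20 hpf and about 18,000 at 48 hpf), used
#' for the worked fold-change example.
#'
#' @return Named numeric vector with elements `n20` and `n48`.
#' @export
reference_counts <- function() c(n20 = 2200, n48 = 18000)

#' Scenario descriptor
#'
#' Perturbation scenarios emulated by the generator:
#' * `control`: wild-type calibration.
#' * `hdac1`: the actin accumulation does not redistribute (basal extent
#'   frozen at the 30-hpf control value at all stages) and tissue thickness
#'   is capped at 55 um; proliferation is unchanged.
#' * `rockout`: the basolateral actin accumulation is abolished and
#'   proliferation is suppressed after the onset time.
#' * `hua`: proliferation is blocked after the onset time (cell-cycle
#'   inhibitors); actin calibration unchanged.
#'
#' @param name one of `"control"`, `"hdac1"`, `"rockout"`, `"hua"`.
#' @param onset_hpf onset of the perturbation (hpf), used by `rockout`/`hua`.
#' @return An object of class `pse_scenario`.
#' @export
scenario <- function(name = c("control", "hdac1", "rockout", "hua"),
                     onset_hpf = 30) {
  name <- match.arg(name)
  structure(list(name = name, onset_hpf = onset_hpf,
                 thickness_cap = if (name == "hdac1") 55 else Inf),
            class = "pse_scenario")
}

#' @export
print.pse_scenario <- function(x, ...) {
  cat("<pse_scenario>", x$name,
      if (is.finite(x$thickness_cap)) sprintf("(thickness cap %g um)", x$thickness_cap),
      if (x$name %in% c("rockout", "hua")) sprintf("(onset %g hpf)", x$onset_hpf),
      "\n")
  invisible(x)
}

# scenario-adjusted calibration row for one stage
scenario_calibration <- function(calib, stage, scen) {
  row <- calib[match_stage(calib$stage_hpf, stage), , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no calibration block for stage ", stage, " hpf")
  if (scen$name == "hdac1") {
    ext30 <- calib$actin_basal_extent_fraction[match_stage(calib$stage_hpf, 30)]
    if (!length(ext30) || is.na(ext30))
      ext30 <- 0.26
    row$actin_basal_extent_fraction <- ext30
    row$mean_thickness <- min(row$mean_thickness, scen$thickness_cap)
  }
  if (scen$name == "rockout") {
    row$actin_basal_extent_fraction <- 0
    if (stage >= scen$onset_hpf) row$mitotic_index <- 0.1 * row$mitotic_index
  }
  if (scen$name == "hua" && stage >= scen$onset_hpf) {
    row$mitotic_index <- 0
  }
  row
}

# stage matching after rounding to 0.1 h
match_stage <- function(stages, stage) {
  which(round(stages, 1) == round(stage, 1))
}
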