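#' Mean interphase cell volume from mitotic diameters
#'
#' Mitotic cells round up to near-spheres, so their widest diameter gives a
#' sphere volume `(pi/6) d^3`. Mitotic cells are on average 10% larger than
#' interphase cells, so the mean sphere volume is multiplied by the
#' interphase correction factor 0.9.
#'
#' @param diameters mitotic cell diameters, um (nonempty).
#' @param correction interphase correction factor (default 0.9).
#' @return Mean interphase cell volume, um^3.
#' @export
interphase_cell_volume <- function(diameters, correction = 0.9) {
  if (!length(diameters)) stop("no mitotic diameters measured")
  stopifnot(all(diameters > 0))
  correction * mean(pi / 6 * diameters^3)
}

#' Mean cross-sectional cell area
#'
#' Apical and basal tissue areas divided by the total cell number give the
#' average apical and basal cell endfoot areas; their arithmetic mean is the
#' mean cross-sectional cell area. The basal area is the total surface area
#' minus the apical area.
#'
#' @param apical_area apical tissue area, um^2.
#' @param total_surface_area total tissue surface area, um^2.
#' @param n_cells total cell count (> 0).
#' @return Mean cross-sectional cell area, um^2.
#' @export
mean_cell_cross_section <- function(apical_area, total_surface_area, n_cells) {
  stopifnot(n_cells > 0)
  basal_area <- total_surface_area - apical_area
  if (basal_area <= 0)
    stop("basal area (total - apical) must be positive")
  (apical_area / n_cells + basal_area / n_cells) / 2
}

#' Corrected mean tissue thickness
#'
#' Mean of the sampled thickness positions, decreased by 5% to correct for
#' the thinner ciliary marginal zone around the optic fissure. The
#' correction can be disabled.
#'
#' @param samples thickness samples, um (nonempty).
#' @param correct apply the CMZ correction? (default `TRUE`).
#' @param factor correction factor (default 0.95).
#' @return Corrected mean thickness, um.
#' @export
corrected_thickness <- function(samples, correct = TRUE, factor = 0.95) {
  stopifnot(length(samples) >= 1, all(samples > 0))
  m <- mean(samples)
  if (correct) factor * m else m
}

#' Aspect ratio of a height and an area
#'
#' Height divided by the square root of the area. The same operation serves
#' the cell-scale ratio (tissue height over the square root of the mean
#' cell cross-section) and the tissue-scale ratio (tissue height over the
#' square root of the mean tissue area); constancy of the tissue ratio is
#' the operational definition of isotropic growth.
#'
#' @param height um.
#' @param area um^2.
#' @return Dimensionless aspect ratio.
#' @export
aspect_ratio <- function(height, area) {
  stopifnot(height > 0, area > 0)
  height / sqrt(area)
}

#' Nuclear stacking in the nuclear zone
#'
#' Height of the zone containing nuclear signal divided by the mean nuclear
#' long (apicobasal) axis; reported unrounded.
#'
#' @param zone_height um.
#' @param nuclear_long_axis um.
#' @return Average number of stacked nuclei (real-valued).
#' @export
nuclear_stacking <- function(zone_height, nuclear_long_axis) {
  stopifnot(zone_height > 0, nuclear_long_axis > 0)
  zone_height / nuclear_long_axis
}

#' Apical-to-basal nuclear layer count
#'
#' Total tissue thickness divided by the mean nuclear long axis: the number
#' of nuclear layers the full apicobasal axis could hold.
#'
#' @param thickness um.
#' @param nuclear_long_axis um.
#' @return Real-valued layer count.
#' @export
apical_to_basal_layers <- function(thickness, nuclear_long_axis) {
  stopifnot(thickness > 0, nuclear_long_axis > 0)
  thickness / nuclear_long_axis
}

#' Per-stage derived cell metrics from a stage table
#'
#' Pools embryos per stage and derives the cell-level metrics: mean
#' interphase cell volume (from mitotic diameters), mean cross-sectional
#' cell area, corrected thickness, cell density, cell and tissue aspect
#' ratios, nuclear stacking, and apical-to-basal layer count.
#'
#' @param table a [stage_table()].
#' @param thickness_correction apply the CMZ correction?
#' @param cmz_factor CMZ correction factor.
#' @return data.frame, one row per stage.
#' @export
derive_cell_metrics <- function(table, thickness_correction = TRUE,
                                cmz_factor = 0.95) {
  stopifnot(inherits(table, "stage_table"))
  out <- lapply(table$stages, function(stage) {
    rows <- Filter(function(m) round(m$stage_hpf, 1) == stage, table$rows)
    V <- mean(vapply(rows, `[[`, numeric(1), "tissue_volume"))
    N <- mean(vapply(rows, `[[`, numeric(1), "n_cells"))
    d <- unlist(lapply(rows, `[[`, "mitotic_diameters"))
    vcell <- if (length(d)) interphase_cell_volume(d) else NA_real_
    xsec <- mean(vapply(rows, function(m)
      mean_cell_cross_section(m$apical_area, m$total_surface_area, m$n_cells),
      numeric(1)))
    h <- mean(vapply(rows, function(m)
      corrected_thickness(m$thickness_samples, thickness_correction,
                          cmz_factor), numeric(1)))
    area <- mean(vapply(rows, function(m)
      (m$apical_area + (m$total_surface_area - m$apical_area)) / 2,
      numeric(1)))
    nz <- mean(vapply(rows, `[[`, numeric(1), "nuclear_zone_height"))
    na_ <- mean(vapply(rows, `[[`, numeric(1), "nuclear_long_axis"))
    data.frame(stage_hpf = stage, mean_tissue_volume = V, mean_cells = N,
               mean_cell_volume = vcell, mean_cell_cross_section = xsec,
               corrected_thickness = h, mean_tissue_area = area,
               cell_density = N / V,
               cell_aspect_ratio = aspect_ratio(h, xsec),
               tissue_aspect_ratio = aspect_ratio(h, area),
               nuclear_stacking = nuclear_stacking(nz, na_),
               apical_to_basal_layers = apical_to_basal_layers(h, na_))
  })
  do.call(rbind, out)
}

#' Cumulative logarithmic growth-rate decomposition
#'
#' For each quantity Q and stage interval, the rate contribution is
#' `ln(Q_{i+1}/Q_i)`, accumulated from the first stage. Two balance
#' identities are reported: the cell balance `ln V = ln N + ln v` (tissue
#' volume = cell number x cell volume) and the geometric balance
#' `ln V = ln A + ln h` (tissue volume = tissue area x height). Residuals
#' are the cumulative-volume rate minus the sum of the two component rates;
#' they vanish identically when the inputs satisfy the identity by
#' construction.
#'
#' @param stage_means data.frame with columns `stage_hpf`,
#'   `tissue_volume`, `n_cells`, `cell_volume`, `tissue_area`,
#'   `tissue_height` (per-stage means; >= 2 stages, strictly increasing,
#'   all positive).
#' @return data.frame of class `log_rate_series`: cumulative log rates
#'   `cum_volume`, `cum_cells`, `cum_cell_volume`, `cum_area`,
#'   `cum_height`, and residuals `residual_cells`, `residual_geometry`.
#' @export
log_rate_decomposition <- function(stage_means) {
  need <- c("stage_hpf", "tissue_volume", "n_cells", "cell_volume",
            "tissue_area", "tissue_height")
  stopifnot(all(need %in% names(stage_means)), nrow(stage_means) >= 2)
  sm <- stage_means[order(stage_means$stage_hpf), need]
  if (is.unsorted(sm$stage_hpf, strictly = TRUE))
    stop("stages must be strictly increasing")
  if (any(as.matrix(sm[, -1]) <= 0)) stop("all quantities must be positive")
  cum <- function(q) c(0, cumsum(diff(log(q))))
  out <- data.frame(
    stage_hpf = sm$stage_hpf,
    cum_volume = cum(sm$tissue_volume),
    cum_cells = cum(sm$n_cells),
    cum_cell_volume = cum(sm$cell_volume),
    cum_area = cum(sm$tissue_area),
    cum_height = cum(sm$tissue_height))
  out$residual_cells <- out$cum_volume - (out$cum_cells + out$cum_cell_volume)
  out$residual_geometry <- out$cum_volume - (out$cum_area + out$cum_height)
  class(out) <- c("log_rate_series", "data.frame")
  out
}

#' Pooled standard deviation of the cumulative log-rate series
#'
#' Delta-method uncertainty of each cumulative log rate from per-stage
#' coefficients of variation: the variance of `ln(Q_i/Q_0)` is approximately
#' `cv_i^2 + cv_0^2` (embryo-level SD band, matching mean +/- SD displays).
#' The pooled SD of the balance residual sums the three component
#' variances.
#'
#' @param cvs data.frame with columns `stage_hpf` and per-quantity CV
#'   columns named as in [log_rate_decomposition()] inputs.
#' @param quantities the three series entering a balance identity.
#' @return Numeric vector: pooled residual SD per stage.
#' @export
pooled_rate_sd <- function(cvs, quantities = c("tissue_volume", "n_cells",
                                               "cell_volume")) {
  stopifnot(all(c("stage_hpf", quantities) %in% names(cvs)))
  v <- rowSums(sapply(quantities, function(q) cvs[[q]]^2 + cvs[[q]][1]^2))
  sqrt(v)
}

#' Exponential growth fit
#'
#' Least-squares fit of `ln V` against time. The doubling time is
#' `ln 2 / rate` (undefined, reported as `NA`, when the rate is not
#' positive); the fold change is `exp(rate * span)` over the sampled time
#' span.
#'
#' @param times hpf (>= 3 points).
#' @param volumes um^3 (> 0).
#' @return List with `rate` (1/h), `rate_se`, `doubling_time` (h),
#'   `fold_change`, and the underlying `fit` (an `lm`).
#' @export
exponential_growth_fit <- function(times, volumes) {
  stopifnot(length(times) == length(volumes), length(times) >= 3)
  if (any(volumes <= 0)) stop("volumes must be positive")
  fit <- stats::lm(log(volumes) ~ times)
  rate <- unname(stats::coef(fit)[2])
  # slope SE computed directly (avoids summary.lm noise on exact fits)
  rss <- sum(stats::residuals(fit)^2)
  se <- sqrt(rss / (length(times) - 2) / sum((times - mean(times))^2))
  span <- max(times) - min(times)
  list(rate = rate, rate_se = se,
       doubling_time = if (rate > 0) log(2) / rate else NA_real_,
       fold_change = exp(rate * span), fit = fit)
}
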