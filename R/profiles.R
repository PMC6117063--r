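#' Normalize an apicobasal intensity profile
#'
#' Positions are rescaled to [0, 1] (0 = apical surface, 1 = basal
#' surface), intensities min-max scaled to [0, 1], and the profile
#' resampled to a fixed 100-point grid by linear interpolation, so that
#' profiles from different embryos share a common axis.
#'
#' @param positions raw axis positions (any monotone scale, >= 2 values).
#' @param intensities raw intensities (non-constant).
#' @param channel `"actin"` or `"nuclear"`.
#' @param stage_hpf,embryo_id metadata carried along.
#' @param grid_points grid size (default 100).
#' @return Object of class `apicobasal_profile`: list with `positions`,
#'   `intensities`, `channel`, `stage_hpf`, `embryo_id`.
#' @export
normalize_profile <- function(positions, intensities, channel = "actin",
                              stage_hpf = NA_real_, embryo_id = NA_character_,
                              grid_points = 100L) {
  stopifnot(length(positions) == length(intensities), length(positions) >= 2)
  o <- order(positions)
  positions <- positions[o]; intensities <- intensities[o]
  if (any(duplicated(positions))) stop("positions must be strictly increasing")
  rng <- range(intensities)
  if (diff(rng) <= 0)
    stop("constant intensity: min-max normalization undefined")
  p <- (positions - positions[1]) / diff(range(positions))
  grid <- seq(0, 1, length.out = grid_points)
  y <- stats::approx(p, intensities, xout = grid)$y
  y <- (y - min(y)) / (max(y) - min(y))
  structure(list(positions = grid, intensities = y, channel = channel,
                 stage_hpf = stage_hpf, embryo_id = embryo_id),
            class = "apicobasal_profile")
}

#' @export
print.apicobasal_profile <- function(x, ...) {
  cat("<apicobasal_profile>", x$channel, "| stage", x$stage_hpf, "hpf |",
      length(x$positions), "grid points\n")
  invisible(x)
}

#' Average profiles of one stage and channel
#'
#' Pointwise mean and standard error of the mean across profiles sharing
#' the common normalized grid, re-normalized to [0, 1] so the average is
#' itself a valid normalized profile.
#'
#' @param profiles list of `apicobasal_profile` objects on the same grid.
#' @return List of class `apicobasal_profile` with an extra `sem` element.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "apicobasal_profile")))
  Y <- vapply(profiles, `[[`, numeric(length(profiles[[1]]$positions)),
              "intensities")
  Y <- matrix(Y, ncol = length(profiles))
  m <- rowMeans(Y)
  sem <- if (ncol(Y) > 1) apply(Y, 1, stats::sd) / sqrt(ncol(Y)) else
    rep(0, nrow(Y))
  m01 <- (m - min(m)) / (max(m) - min(m))
  out <- structure(list(positions = profiles[[1]]$positions,
                        intensities = m01, sem = sem / (max(m) - min(m)),
                        channel = profiles[[1]]$channel,
                        stage_hpf = profiles[[1]]$stage_hpf,
                        embryo_id = "mean"),
                   class = "apicobasal_profile")
  out
}

#' Detect the basal actin accumulation zone
#'
#' Boundary rule: the lateral baseline is the lower quartile of intensity
#' over the interior of the axis (positions 0.15-0.95, robust to plateaus
#' covering up to ~60% of the axis and blind to the apical cortical peak),
#' the basal plateau level is the mean of the two highest intensities over
#' the basal 30% (positions >= 0.7), and the boundary is the most-apical,
#' linearly interpolated position at which the contiguous basal region
#' first exceeds baseline + half the plateau-baseline height. The zone
#' extent is 1 - boundary; a profile whose basal elevation is less than
#' 10% of the normalized intensity range yields extent 0 with an `absent`
#' flag.
#'
#' @param profile a normalized `apicobasal_profile` (actin channel).
#' @param tissue_height optional tissue height (um) to convert the extent
#'   to micrometers.
#' @return List of class `zone_call`: `extent_fraction`, `extent_um`,
#'   `boundary`, `absent`, `baseline`, `plateau`.
#' @export
detect_basal_zone <- function(profile, tissue_height = NULL) {
  stopifnot(inherits(profile, "apicobasal_profile"))
  x <- profile$positions; y <- profile$intensities
  baseline <- unname(stats::quantile(y[x >= 0.15 & x <= 0.95], 0.25))
  basal <- sort(y[x >= 0.7], decreasing = TRUE)
  plateau <- mean(basal[1:2])
  thr <- baseline + 0.5 * (plateau - baseline)
  absent <- plateau - baseline < 0.1 || y[length(y)] <= thr
  if (absent) {
    out <- list(extent_fraction = 0, extent_um = if (!is.null(tissue_height)) 0,
                boundary = 1, absent = TRUE, baseline = baseline,
                plateau = plateau)
    class(out) <- "zone_call"
    return(out)
  }
  above <- y > thr
  # contiguous run containing the basal end
  i <- length(y)
  while (i > 1 && above[i - 1]) i <- i - 1
  boundary <- if (i == 1) 0 else {
    # interpolate the threshold crossing between grid points i-1 and i
    x[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
  }
  out <- list(extent_fraction = 1 - boundary,
              extent_um = if (!is.null(tissue_height))
                (1 - boundary) * tissue_height,
              boundary = boundary, absent = FALSE, baseline = baseline,
              plateau = plateau)
  class(out) <- "zone_call"
  out
}

#' @export
print.zone_call <- function(x, ...) {
  if (x$absent) cat("<zone_call> basal accumulation absent\n")
  else cat(sprintf("<zone_call> basal extent %.1f%% of axis (boundary %.3f)%s\n",
                   100 * x$extent_fraction, x$boundary,
                   if (!is.null(x$extent_um)) sprintf(", %.1f um", x$extent_um) else ""))
  invisible(x)
}

#' Concordance of the actin zone with the nuclear exclusion zone
#'
#' Pearson correlation between actin and nuclear intensities over the basal
#' 30% of the axis (expected strongly negative when the actin plateau
#' excludes nuclei), plus the absolute disagreement between the actin zone
#' boundary and the nuclear falling-edge boundary (half-height crossing of
#' the nuclear profile between its lateral level and basal floor).
#'
#' @param actin,nuclear normalized `apicobasal_profile`s on the common
#'   grid.
#' @return List: `correlation`, `actin_boundary`, `nuclear_boundary`
#'   (`NA` when the nuclear signal never falls, i.e. nuclei occupy the full
#'   axis), `boundary_gap`.
#' @export
exclusion_zone_concordance <- function(actin, nuclear) {
  stopifnot(inherits(actin, "apicobasal_profile"),
            inherits(nuclear, "apicobasal_profile"),
            length(actin$positions) == length(nuclear$positions))
  x <- actin$positions
  sel <- x >= 0.7
  rho <- stats::cor(actin$intensities[sel], nuclear$intensities[sel])
  az <- detect_basal_zone(actin)
  yn <- nuclear$intensities
  lat <- stats::median(yn[x >= 0.3 & x <= 0.7])
  floor_ <- stats::median(yn[x >= 0.95])
  nb <- NA_real_
  if (lat - floor_ > 0.25 * max(1e-12, lat)) {
    thr <- floor_ + 0.5 * (lat - floor_)
    below <- yn < thr
    i <- length(yn)
    while (i > 1 && below[i - 1]) i <- i - 1
    nb <- if (i == 1) 0 else
      x[i - 1] + (thr - yn[i - 1]) / (yn[i] - yn[i - 1]) * (x[i] - x[i - 1])
  }
  list(correlation = rho, actin_boundary = az$boundary, nuclear_boundary = nb,
       boundary_gap = if (is.na(nb)) NA_real_ else abs(az$boundary - nb))
}

#' Cortical signal ratios from region strip profiles
#'
#' Peaks (local maxima with prominence at least 10% of the region's
#' intensity range) are taken to represent the cortical signal in each
#' strip; the ratios of mean peak heights basal/lateral and apical/lateral
#' quantify actin redistribution from lateral interfaces toward the
#' apicobasal belts.
#'
#' @param apical,basal,lateral numeric intensity traces along the
#'   respective tissue strips.
#' @param prominence_frac prominence floor as a fraction of the region
#'   range (default 0.1).
#' @return List of class `cortical_ratios`: `basal_to_lateral`,
#'   `apical_to_lateral`, and per-region mean peak heights.
#' @export
cortical_ratios <- function(apical, basal, lateral, prominence_frac = 0.1) {
  peak_mean <- function(y, name) {
    pk <- find_peaks(y, min_prominence = prominence_frac * diff(range(y)))
    if (!nrow(pk)) stop("no peaks found in ", name, " region")
    mean(pk$height)
  }
  ap <- peak_mean(apical, "apical")
  ba <- peak_mean(basal, "basal")
  la <- peak_mean(lateral, "lateral")
  structure(list(basal_to_lateral = ba / la, apical_to_lateral = ap / la,
                 apical_peak = ap, basal_peak = ba, lateral_peak = la),
            class = "cortical_ratios")
}

#' @export
print.cortical_ratios <- function(x, ...) {
  cat(sprintf("<cortical_ratios> basal/lateral %.2f, apical/lateral %.2f\n",
              x$basal_to_lateral, x$apical_to_lateral))
  invisible(x)
}
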