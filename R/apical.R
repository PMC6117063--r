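#' Algebraic least-squares sphere fit
#'
#' Fits a sphere to 3D points by the linear (Coope) formulation:
#' `|x|^2 = 2 c . x + (R^2 - |c|^2)` is linear in the center `c` and an
#' intercept, solved by least squares. Degenerate (e.g. coplanar)
#' configurations are rejected.
#'
#' @param points n x 3 numeric matrix (um), n >= 4, non-coplanar.
#' @return List of class `sphere_fit`: `center` (3-vector), `radius`,
#'   `rms_residual` (um, radial).
#' @export
fit_sphere <- function(points) {
  if (inherits(points, "mitotic_points")) points <- points$points
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 4, all(is.finite(points)))
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_ <- qr(A)
  if (qr_$rank < 4)
    stop("degenerate point configuration: sphere fit is underdetermined")
  sol <- qr.coef(qr_, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate point configuration: non-positive fitted radius")
  radius <- sqrt(r2)
  r_i <- sqrt(rowSums(sweep(points, 2, center)^2))
  # near-coplanar clouds solve the linear system but with wild radii
  if (stats::sd(r_i) / radius > 0.9)
    stop("degenerate point configuration: points do not constrain a sphere")
  structure(list(center = unname(center), radius = unname(radius),
                 rms_residual = sqrt(mean((r_i - radius)^2))),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> center (%.2f, %.2f, %.2f) um, radius %.2f um, rms %.3f um\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}

#' Lambert azimuthal equal-area projection of points on a sphere
#'
#' Points are expressed as (colatitude theta from the pole, azimuth phi)
#' on the fitted sphere and mapped to the plane by
#' `rho = 2 R sin(theta/2)`, `(rho cos phi, rho sin phi)`. Equal
#' solid-angle patches map to equal planar areas, so planar point density
#' is proportional to per-area density on the sphere. The antipode
#' (theta = pi) maps to the boundary circle `rho = 2R` and is flagged.
#'
#' @param points n x 3 matrix (um) or a `mitotic_points` object.
#' @param fit a [fit_sphere()] result.
#' @param pole unit 3-vector; default: from the center through the point
#'   centroid.
#' @return data.frame `x`, `y` (um in the projection plane), `theta`,
#'   `phi`, `antipodal` (logical).
#' @export
project_equal_area <- function(points, fit, pole = NULL) {
  if (inherits(points, "mitotic_points")) points <- points$points
  points <- as.matrix(points)
  stopifnot(inherits(fit, "sphere_fit"))
  v <- sweep(points, 2, fit$center)
  if (is.null(pole)) {
    pole <- colMeans(v)
    if (sqrt(sum(pole^2)) < 1e-12) pole <- c(0, 0, 1)
  }
  pole <- pole / sqrt(sum(pole^2))
  r <- sqrt(rowSums(v^2))
  ct <- pmin(1, pmax(-1, (v %*% pole) / r))
  theta <- acos(ct)
  # azimuth in the plane orthogonal to the pole
  ref <- if (abs(pole[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * pole) * pole; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(pole[2] * e1[3] - pole[3] * e1[2],
          pole[3] * e1[1] - pole[1] * e1[3],
          pole[1] * e1[2] - pole[2] * e1[1])
  phi <- atan2(v %*% e2, v %*% e1)
  rho <- 2 * fit$radius * sin(theta / 2)
  anti <- abs(theta - pi) < 1e-9
  if (any(anti))
    warning(sum(anti), " point(s) at the projection antipode mapped to the boundary circle")
  data.frame(x = as.numeric(rho * cos(phi)), y = as.numeric(rho * sin(phi)),
             theta = as.numeric(theta), phi = as.numeric(phi),
             antipodal = anti)
}

#' Binned density heatmap of projected points
#'
#' Counts per square bin, normalized per unit projected area so that
#' `sum(density * bin_area)` equals the point count. Optional Gaussian
#' smoothing with a stated bandwidth (applied to the count grid with
#' renormalization of the kernel mass, so mass is conserved away from the
#' boundary).
#'
#' @param projected data.frame with `x`, `y` (um), e.g. from
#'   [project_equal_area()].
#' @param bins bins per axis.
#' @param limits plot limits `c(lo, hi)` applied to both axes; default the
#'   symmetric range of the data.
#' @param smooth_bandwidth Gaussian sigma in bin units; 0 disables.
#' @return List of class `heatmap_grid`: `density` (bins x bins), `counts`,
#'   `xbreaks`, `ybreaks`, `bin_area`, `n`.
#' @export
density_heatmap <- function(projected, bins = 8, limits = NULL,
                            smooth_bandwidth = 0) {
  x <- projected$x; y <- projected$y
  if (is.null(limits)) {
    r <- max(1e-9, max(abs(c(x, y, 1e-9))))
    limits <- c(-r, r)
  }
  br <- seq(limits[1], limits[2], length.out = bins + 1)
  cnt <- matrix(0, bins, bins)
  if (length(x)) {
    ix <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1), bins)
    iy <- pmin(pmax(findInterval(y, br, rightmost.closed = TRUE), 1), bins)
    for (k in seq_along(ix)) cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1
  }
  sm <- cnt
  if (smooth_bandwidth > 0) {
    s <- smooth_bandwidth
    w <- stats::dnorm(seq(-ceiling(3 * s), ceiling(3 * s)), 0, s)
    conv1 <- function(m) {
      # separable convolution; each source bin's clipped kernel is
      # renormalized so its mass stays inside the grid (mass-conserving)
      apply(m, 2, function(col) {
        out <- numeric(length(col))
        off <- seq_along(w) - ceiling(3 * s) - 1
        for (j in seq_along(col)) {
          if (col[j] == 0) next
          i <- j + off
          ok <- i >= 1 & i <= length(col)
          out[i[ok]] <- out[i[ok]] + col[j] * w[ok] / sum(w[ok])
        }
        out
      })
    }
    sm <- t(conv1(t(conv1(cnt))))
  }
  bin_area <- diff(br)[1]^2
  structure(list(density = sm / bin_area, counts = cnt, xbreaks = br,
                 ybreaks = br, bin_area = bin_area, n = length(x)),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat("<heatmap_grid>", nrow(x$density), "x", ncol(x$density), "bins,",
      x$n, "events, bin area", signif(x$bin_area, 4), "um^2\n")
  invisible(x)
}

#' Chi-square test of heatmap uniformity on equal-area annuli
#'
#' Partitions the projected disk of a spherical cap into equal-area annuli
#' (equal-area implies equal expected counts under uniform per-area
#' density) and tests the observed annulus counts against uniformity.
#'
#' @param projected output of [project_equal_area()].
#' @param fit the [fit_sphere()] used for projection.
#' @param theta_max cap colatitude limit (radians).
#' @param n_annuli number of equal-area annuli.
#' @return `htest` from [stats::chisq.test()].
#' @export
annulus_uniformity_test <- function(projected, fit, theta_max, n_annuli = 10) {
  rho <- sqrt(projected$x^2 + projected$y^2)
  rho_max <- 2 * fit$radius * sin(theta_max / 2)
  edges <- rho_max * sqrt(seq(0, 1, length.out = n_annuli + 1))
  counts <- table(cut(pmin(rho, rho_max), edges, include.lowest = TRUE))
  stats::chisq.test(as.numeric(counts))
}

#' Division-angle statistics (axial data)
#'
#' Division axes have no sign, so angles are treated as axial with period
#' pi: angles are doubled before computing the mean resultant length and
#' the Rayleigh uniformity test. Rose-plot counts use configurable sector
#' widths on the original axial scale, pooling antipodal directions.
#'
#' @param angles radians (in-plane).
#' @param sector_width_deg rose sector width, degrees (default 10).
#' @return List: `rose` (data.frame `sector_mid_deg`, `count`),
#'   `resultant_length` (of the doubled angles), `p_value` (Rayleigh on
#'   doubled angles).
#' @export
division_angle_stats <- function(angles, sector_width_deg = 10) {
  stopifnot(is.numeric(angles))
  ax <- angles %% pi
  breaks <- seq(0, 180, by = sector_width_deg)
  cnt <- table(cut(ax * 180 / pi, breaks, include.lowest = TRUE, right = FALSE))
  rt <- rayleigh_test(2 * ax)
  list(rose = data.frame(sector_mid_deg = utils::head(breaks, -1) +
                           sector_width_deg / 2,
                         count = as.numeric(cnt)),
       resultant_length = rt$r, p_value = rt$p.value)
}

#' Apical surface occupancy by mitotic cells
#'
#' Mitotic cells round up at the apical surface; their mean cross-section
#' (a circle at the measured widest diameter) times the mitotic count,
#' divided by the tissue-wide apical surface area, gives the occupied
#' fraction.
#'
#' @param mitotic_diameters measured diameters, um (mean is used); may be
#'   empty only when `n_mitotic` is 0.
#' @param n_mitotic number of mitotic cells.
#' @param apical_area apical tissue surface area, um^2 (> 0).
#' @return Occupied fraction (>= 0).
#' @export
apical_occupancy <- function(mitotic_diameters, n_mitotic, apical_area) {
  stopifnot(apical_area > 0, n_mitotic >= 0)
  if (n_mitotic == 0) return(0)
  if (!length(mitotic_diameters))
    stop("mitotic diameters required when n_mitotic > 0")
  dbar <- mean(mitotic_diameters)
  n_mitotic * pi * (dbar / 2)^2 / apical_area
}

#' Volume of a truncated cone (frustum)
#'
#' `V = (pi/3) h (R^2 + r^2 + R r)`, the volume of the tissue unit under a
#' rounded mitotic cell of apical radius `R` narrowing to basal radius `r`
#' over height `h`.
#'
#' @param h height, um (> 0).
#' @param R large (apical) base radius, um.
#' @param r small (basal) base radius, um (`0 <= r <= R`).
#' @return Volume, um^3.
#' @export
frustum_volume <- function(h, R, r) {
  stopifnot(h > 0, R > 0, r >= 0)
  if (r > R) stop("small base radius r exceeds large base radius R")
  pi / 3 * h * (R^2 + r^2 + R * r)
}

#' Mitotic-frustum "proliferative trap" analysis
#'
#' Compares the number of cells measured inside the mitotic frustum
#' (tissue cell density x frustum volume) against the maximal number whose
#' apical mitoses can be accommodated by cell-cycle timing,
#' `N_max = (T_CC - T_M) / T_M`. A proliferative trap exists only when the
#' measured count strictly exceeds the maximum; equality is reported as
#' "at capacity", not a trap.
#'
#' @param h mean tissue height, um.
#' @param R mean mitotic cell radius (large base), um.
#' @param r small base radius, um (large base divided by the
#'   apical-to-basal area ratio, when derived from tissue areas).
#' @param cell_density cells per um^3.
#' @param T_CC mean cell-cycle length, h.
#' @param T_M mean mitosis duration, h (`0 < T_M < T_CC`).
#' @return List of class `trap_result`: `n_measured`, `n_max`, `trap`
#'   (logical), `at_capacity` (logical).
#' @export
trap_analysis <- function(h, R, r, cell_density, T_CC, T_M) {
  stopifnot(T_CC > T_M, T_M > 0, cell_density >= 0)
  n_measured <- cell_density * frustum_volume(h, R, r)
  n_max <- (T_CC - T_M) / T_M
  structure(list(n_measured = n_measured, n_max = n_max,
                 trap = n_measured > n_max,
                 at_capacity = isTRUE(all.equal(n_measured, n_max))),
            class = "trap_result")
}

#' @export
print.trap_result <- function(x, ...) {
  cat(sprintf("<trap_result> measured %.2f vs max %.2f cells in frustum: %s\n",
              x$n_measured, x$n_max,
              if (x$trap) "TRAP" else if (x$at_capacity) "at capacity" else "no trap"))
  invisible(x)
}

#' Per-stage trap analysis of a stage table
#'
#' Derives the frustum geometry from stage means: height from corrected
#' thickness, large base from the mean mitotic diameter, small base from
#' the large base divided by the apical-to-basal area ratio, density from
#' cell count over tissue volume; cycle parameters from the supplied
#' per-stage cell-cycle statistics.
#'
#' @param table a [stage_table()].
#' @param cycle_stats data.frame with `stage_hpf`, `mean_cycle`,
#'   `mean_mitosis` covering the table's stages.
#' @param thickness_correction,cmz_factor passed to [corrected_thickness()].
#' @return data.frame, one row per stage, with the trap verdict.
#' @export
trap_by_stage <- function(table, cycle_stats, thickness_correction = TRUE,
                          cmz_factor = 0.95) {
  stopifnot(inherits(table, "stage_table"))
  out <- lapply(table$stages, function(stage) {
    rows <- Filter(function(m) round(m$stage_hpf, 1) == stage, table$rows)
    h <- mean(vapply(rows, function(m)
      corrected_thickness(m$thickness_samples, thickness_correction,
                          cmz_factor), numeric(1)))
    d <- unlist(lapply(rows, `[[`, "mitotic_diameters"))
    if (!length(d)) stop("stage ", stage, ": no mitotic diameters")
    R <- mean(d) / 2
    ratio <- mean(vapply(rows, function(m)
      m$apical_area / (m$total_surface_area - m$apical_area), numeric(1)))
    r <- R / ratio
    r <- min(r, R)                      # frustum narrows basally when apical > basal
    dens <- mean(vapply(rows, function(m) m$n_cells / m$tissue_volume,
                        numeric(1)))
    cs <- cycle_stats[match_stage(cycle_stats$stage_hpf, stage), ]
    if (nrow(cs) != 1) stop("stage ", stage, ": missing cycle statistics")
    tr <- trap_analysis(h, R, r, dens, cs$mean_cycle, cs$mean_mitosis)
    data.frame(stage_hpf = stage, n_measured = tr$n_measured,
               n_max = tr$n_max, trap = tr$trap)
  })
  do.call(rbind, out)
}
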