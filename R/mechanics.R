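#' Tension parameters of the truncated-cone cell-shape model
#'
#' Cells are modelled as truncated cones with an apical line tension
#' `lambda_a` acting on the apical perimeter, a basal line tension
#' `lambda_b` on the basal perimeter, and a lateral surface tension `T_l`
#' on the lateral face. Units are arbitrary but consistent (force and
#' force/length); only the ratio `(lambda_a + lambda_b) / T_l` (a length)
#' sets the shape at fixed volume.
#'
#' @param lambda_a,lambda_b apical/basal line tensions (> 0).
#' @param T_l lateral surface tension (> 0).
#' @return List of class `tension_params`.
#' @export
tension_params <- function(lambda_a, lambda_b, T_l) {
  stopifnot(lambda_a > 0, lambda_b > 0, T_l > 0)
  structure(list(lambda_a = lambda_a, lambda_b = lambda_b, T_l = T_l),
            class = "tension_params")
}

# energy of a truncated cone (r_a apical radius, r_b basal radius, h height)
cone_energy <- function(r_a, r_b, h, tp) {
  slant <- sqrt(h^2 + (r_b - r_a)^2)
  2 * pi * r_a * tp$lambda_a + 2 * pi * r_b * tp$lambda_b +
    tp$T_l * pi * (r_a + r_b) * slant
}

cone_height <- function(r_a, r_b, V) 3 * V / (pi * (r_a^2 + r_b^2 + r_a * r_b))

#' Equilibrium cell shape from tension balance
#'
#' Minimizes the mechanical energy
#' `E = 2 pi r_a lambda_a + 2 pi r_b lambda_b + T_l pi (r_a + r_b) sqrt(h^2 + (r_b - r_a)^2)`
#' over truncated cones of fixed volume `V` (height eliminated through the
#' frustum volume relation). When `area_ratio` is supplied, the apical to
#' basal endfoot area ratio `(r_a/r_b)^2` is held at that value (the
#' constant measured area ratio), reducing the search to one dimension;
#' otherwise both radii are free.
#'
#' In the cylinder-constrained case (`area_ratio = 1`) the problem has the
#' closed form `h = (lambda_a + lambda_b) / T_l`, independent of volume,
#' which the numerical minimizer reproduces; the closed form is used as an
#' internal oracle in the package tests, not as the solver.
#'
#' @param V cell volume, um^3 (> 0).
#' @param tensions a [tension_params()].
#' @param area_ratio optional fixed apical-to-basal area ratio
#'   `(r_a/r_b)^2`.
#' @param tol relative tolerance on the objective (default 1e-10).
#' @return List of class `cell_shape`: `r_a`, `r_b`, `h`, `V`, `energy`.
#' @export
cell_shape_from_tensions <- function(V, tensions, area_ratio = NULL,
                                     tol = 1e-10) {
  stopifnot(V > 0, inherits(tensions, "tension_params"))
  lam <- tensions$lambda_a + tensions$lambda_b
  # cylinder solution provides the bracketing length scale
  r_cyl <- sqrt(tensions$T_l * V / (pi * lam))
  lo <- r_cyl / 50; hi <- r_cyl * 50
  if (!is.null(area_ratio)) {
    stopifnot(area_ratio > 0)
    s <- sqrt(area_ratio)               # r_a / r_b
    obj <- function(r_b) {
      r_a <- s * r_b
      cone_energy(r_a, r_b, cone_height(r_a, r_b, V), tensions)
    }
    opt <- stats::optimize(obj, c(lo, hi), tol = max(1e-12, 1e-7 * r_cyl))
    if (opt$minimum < lo * 1.01 || opt$minimum > hi * 0.99)
      stop("cell shape solver did not converge: minimum at search boundary ",
           "(r_b = ", signif(opt$minimum, 4), ")")
    r_b <- opt$minimum; r_a <- s * r_b
  } else {
    obj2 <- function(par) {
      r_a <- exp(par[1]); r_b <- exp(par[2])
      cone_energy(r_a, r_b, cone_height(r_a, r_b, V), tensions)
    }
    opt <- stats::optim(log(c(r_cyl, r_cyl)), obj2, method = "Nelder-Mead",
                        control = list(reltol = tol, maxit = 5000))
    if (opt$convergence != 0)
      stop("cell shape solver did not converge: optim code ", opt$convergence)
    r_a <- exp(opt$par[1]); r_b <- exp(opt$par[2])
  }
  h <- cone_height(r_a, r_b, V)
  structure(list(r_a = r_a, r_b = r_b, h = h, V = V,
                 energy = cone_energy(r_a, r_b, h, tensions)),
            class = "cell_shape")
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf("<cell_shape> r_a %.3f, r_b %.3f, h %.3f um (V %.1f um^3)\n",
              x$r_a, x$r_b, x$h, x$V))
  invisible(x)
}

#' Tension schedule over developmental time
#'
#' The time course of the tension ratio `(lambda_a + lambda_b) / T_l`:
#' constant at `pre_ratio` before `t_transition`, ramping linearly over
#' `ramp_hours` to `post_ratio`, then constant (control); with
#' `post_ratio = pre_ratio` the schedule is constant throughout (the
#' no-redistribution, hdac1-like scenario).
#'
#' @param pre_ratio,post_ratio tension ratios (length units).
#' @param t_transition ramp onset, hpf.
#' @param ramp_hours ramp duration, h.
#' @return Function of class `tension_schedule` mapping time (hpf) to the
#'   ratio.
#' @export
tension_schedule <- function(pre_ratio, post_ratio = pre_ratio,
                             t_transition = 35.5, ramp_hours = 6) {
  stopifnot(pre_ratio > 0, post_ratio > 0, ramp_hours > 0)
  f <- function(t) {
    w <- pmin(pmax((t - t_transition) / ramp_hours, 0), 1)
    pre_ratio + w * (post_ratio - pre_ratio)
  }
  attr(f, "pre_ratio") <- pre_ratio
  attr(f, "post_ratio") <- post_ratio
  attr(f, "t_transition") <- t_transition
  attr(f, "ramp_hours") <- ramp_hours
  class(f) <- c("tension_schedule", "function")
  f
}

#' Calibrate a tension schedule from reference heights
#'
#' Inverts the shape solver so that the solved cell height equals the
#' supplied reference heights at the calibration stages. With one
#' reference the schedule is constant; with two, the first sets the
#' pre-transition plateau and the second the post-transition plateau.
#' Under the cylinder constraint the inversion is exact and closed-form
#' (`ratio = h`); for general `area_ratio` it is solved numerically at the
#' supplied reference volume.
#'
#' @param ref_heights one or two target heights, um.
#' @param t_transition,ramp_hours ramp parameters, see
#'   [tension_schedule()].
#' @param area_ratio apical-to-basal area ratio constraint (default 1,
#'   cylinder).
#' @param V_ref reference cell volume used for non-cylinder inversion.
#' @return A [tension_schedule()].
#' @export
calibrate_schedule <- function(ref_heights, t_transition = 35.5,
                               ramp_hours = 6, area_ratio = 1, V_ref = 300) {
  stopifnot(length(ref_heights) %in% c(1L, 2L), all(ref_heights > 0))
  invert <- function(h_target) {
    if (isTRUE(all.equal(area_ratio, 1))) return(h_target)
    f <- function(ratio) {
      tp <- tension_params(ratio / 2, ratio / 2, 1)
      cell_shape_from_tensions(V_ref, tp, area_ratio = area_ratio)$h - h_target
    }
    stats::uniroot(f, c(h_target / 10, h_target * 10), tol = 1e-9)$root
  }
  pre <- invert(ref_heights[1])
  post <- if (length(ref_heights) == 2) invert(ref_heights[2]) else pre
  tension_schedule(pre, post, t_transition, ramp_hours)
}

#' Coupled tissue trajectory under a tension schedule
#'
#' At each time point the mean cell volume is tissue volume over cell
#' number, the cell height is solved from the tension schedule (cylinder
#' constraint by default, matching the constant measured apical-to-basal
#' area ratio option), the tissue area is cell number times the mean
#' cross-section (equivalently tissue volume over height), and the tissue
#' aspect ratio is height over the square root of the area.
#'
#' @param times time grid, hpf.
#' @param tissue_volume function of time returning tissue volume (um^3),
#'   or a numeric vector on `times`.
#' @param n_cells function of time returning total cell number, or a
#'   numeric vector on `times`.
#' @param schedule a [tension_schedule()].
#' @param area_ratio apical-to-basal area ratio constraint (default 1).
#' @return data.frame of class `tissue_trajectory`: `t`, `ratio`, `h`,
#'   `v_cell`, `area`, `aspect_ratio`.
#' @export
tissue_trajectory <- function(times, tissue_volume, n_cells, schedule,
                              area_ratio = 1) {
  stopifnot(inherits(schedule, "tension_schedule"))
  V <- if (is.function(tissue_volume)) tissue_volume(times) else
    rep_len(tissue_volume, length(times))
  N <- if (is.function(n_cells)) n_cells(times) else
    rep_len(n_cells, length(times))
  stopifnot(all(V > 0), all(N > 0))
  ratio <- schedule(times)
  v_cell <- V / N
  h <- vapply(seq_along(times), function(i) {
    tp <- tension_params(ratio[i] / 2, ratio[i] / 2, 1)
    cell_shape_from_tensions(v_cell[i], tp, area_ratio = area_ratio)$h
  }, numeric(1))
  area <- V / h
  out <- data.frame(t = times, ratio = ratio, h = h, v_cell = v_cell,
                    area = area, aspect_ratio = h / sqrt(area))
  class(out) <- c("tissue_trajectory", "data.frame")
  out
}

#' Net aspect-ratio drift of a trajectory
#'
#' Relative change of the tissue aspect ratio between the first and last
#' time point, `|ar_end - ar_start| / ar_start`. A control trajectory that
#' restores isotropy ends near zero drift even though the ratio dips
#' transiently around the transition; the no-redistribution trajectory
#' drifts monotonically downward.
#'
#' @param traj a [tissue_trajectory()].
#' @return Nonnegative drift fraction.
#' @export
aspect_drift <- function(traj) {
  ar <- traj$aspect_ratio
  abs(ar[length(ar)] - ar[1]) / ar[1]
}

#' Control and no-redistribution trajectory pair
#'
#' Convenience constructor of the two headline mechanics scenarios on a
#' common time grid with exponential tissue-volume growth and the
#' mean-field cell-number trajectory:
#' * `control`: pre-transition plateau solving the 30-hpf reference height;
#'   the post-transition plateau is calibrated so the tissue aspect ratio
#'   returns to its starting value at the end of the trajectory
#'   (redistribution-driven elongation restores isotropy);
#' * `hdac1`: the same pre-transition plateau held constant throughout (no
#'   redistribution), so the height never rises above the 30-hpf value.
#'
#' @param times time grid, hpf.
#' @param V0 tissue volume at `times[1]`, um^3.
#' @param growth_rate exponential volume growth rate, 1/h.
#' @param n_cells_fun function of time giving cell number.
#' @param h_ref reference height at 30 hpf, um (default 55).
#' @param t_transition,ramp_hours ramp parameters.
#' @return List with `control` and `hdac1` trajectories.
#' @export
scenario_trajectories <- function(times = seq(20, 48, by = 0.5), V0 = 960057,
                                  growth_rate = 0.055,
                                  n_cells_fun = function(t)
                                    2177 * exp(log(18000 / 2177) / 28 * (t - 20)),
                                  h_ref = 55, t_transition = 35.5,
                                  ramp_hours = 6) {
  Vf <- function(t) V0 * exp(growth_rate * (t - times[1]))
  # post plateau restoring the starting aspect ratio at the trajectory end:
  # ar = h^{3/2} / sqrt(V), so h_end = (ar_start^2 V_end)^{1/3}
  ar_start <- h_ref^1.5 / sqrt(Vf(times[1]))
  h_end <- (ar_start^2 * Vf(times[length(times)]))^(1 / 3)
  ctrl <- calibrate_schedule(c(h_ref, h_end), t_transition, ramp_hours)
  hd <- calibrate_schedule(h_ref, t_transition, ramp_hours)
  list(control = tissue_trajectory(times, Vf, n_cells_fun, ctrl),
       hdac1 = tissue_trajectory(times, Vf, n_cells_fun, hd))
}
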