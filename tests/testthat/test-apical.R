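test_that("sphere fit recovers exact and noisy spheres and rejects planes", {
  set.seed(31)
  n <- 500
  u <- stats::runif(n, -1, 1); ph <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  dirs <- cbind(s * cos(ph), s * sin(ph), u)
  center <- c(12, -7, 30)
  exact <- sweep(100 * dirs, 2, center, "+")
  f <- fit_sphere(exact)
  expect_equal(f$center, center, tolerance = 1e-9)
  expect_equal(f$radius, 100, tolerance = 1e-9)
  expect_lt(f$rms_residual, 1e-9)

  noisy <- exact + matrix(stats::rnorm(3 * n, 0, 1), n, 3)
  fn <- fit_sphere(noisy)
  expect_lt(abs(fn$radius - 100), 0.2)

  plane <- cbind(stats::runif(50), stats::runif(50), 1)
  expect_error(fit_sphere(plane), "degenerate")
})

test_that("Lambert projection maps colatitudes to the analytic radii", {
  f <- structure(list(center = c(0, 0, 0), radius = 1, rms_residual = 0),
                 class = "sphere_fit")
  pts <- rbind(c(0, 0, 1),            # theta = 0 -> origin
               c(1, 0, 0),            # theta = pi/2 -> radius sqrt(2)
               c(sin(1), 0, cos(1)))  # theta = 1 -> 2 sin(1/2)
  prj <- project_equal_area(pts, f, pole = c(0, 0, 1))
  rho <- sqrt(prj$x^2 + prj$y^2)
  expect_equal(rho, c(0, sqrt(2), 2 * sin(0.5)), tolerance = 1e-12)
  expect_warning(project_equal_area(rbind(c(0, 0, -1)), f, pole = c(0, 0, 1)),
                 "antipode")
})

test_that("projection preserves area: the analytic Jacobian check", {
  # ratio of planar area to solid angle is R^2 for random spherical patches:
  # planar annulus-sector area between (theta1,theta2)x(phi1,phi2) equals
  # R^2 * (cos theta1 - cos theta2) * dphi exactly under the mapping
  R <- 57.3
  for (i in 1:20) {
    th <- sort(stats::runif(2, 0.01, pi - 0.01))
    dphi <- stats::runif(1, 0.05, 2 * pi)
    rho <- 2 * R * sin(th / 2)
    planar <- 0.5 * dphi * (rho[2]^2 - rho[1]^2)
    solid <- dphi * (cos(th[1]) - cos(th[2]))
    expect_equal(planar / solid, R^2, tolerance = 1e-9)
  }
  # and empirically: uniform cap points give uniform equal-area annuli
  pvals <- vapply(1:20, function(s) {
    pts <- generate_mitotic_coordinates(5000, seed = 100 + s)
    sf <- fit_sphere(pts)
    prj <- project_equal_area(pts, sf)
    annulus_uniformity_test(prj, sf, pi / 2)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("heatmap conserves mass exactly unsmoothed and closely when smoothed", {
  pts <- generate_mitotic_coordinates(2000, seed = 41)
  sf <- fit_sphere(pts)
  prj <- project_equal_area(pts, sf)
  hm <- density_heatmap(prj, bins = 8)
  expect_equal(sum(hm$density) * hm$bin_area, 2000)
  expect_true(all(hm$density >= 0))

  hs <- density_heatmap(prj, bins = 16, smooth_bandwidth = 1)
  expect_equal(sum(hs$density) * hs$bin_area, 2000, tolerance = 1e-6)

  empty <- density_heatmap(data.frame(x = numeric(0), y = numeric(0)),
                           bins = 4)
  expect_equal(sum(empty$density), 0)
  one <- density_heatmap(data.frame(x = 0.1, y = 0.1), bins = 2,
                         limits = c(-1, 1))
  expect_equal(max(one$density), 1 / one$bin_area)

  # uniform sampling spreads events evenly: bin densities inside the
  # projected cap have a modest coefficient of variation
  pts5 <- generate_mitotic_coordinates(5000, seed = 42)
  prj5 <- project_equal_area(pts5, fit_sphere(pts5))
  h5 <- density_heatmap(prj5, bins = 8)
  rho_max <- max(sqrt(prj5$x^2 + prj5$y^2))
  mids <- (utils::head(h5$xbreaks, -1) + utils::tail(h5$xbreaks, -1)) / 2
  inside <- outer(mids^2, mids^2, "+") < (0.85 * rho_max)^2
  d <- h5$density[inside]
  expect_lt(stats::sd(d) / mean(d), 0.25)
})

test_that("division angles are treated as axial data", {
  s <- division_angle_stats(rep(0.7, 40))
  expect_equal(s$resultant_length, 1, tolerance = 1e-12)
  expect_lt(s$p_value, 1e-6)
  u <- division_angle_stats(generate_division_angles(1000, 0, seed = 44))
  expect_lt(u$resultant_length, 0.1)
  # angles at 0 and pi are the same axis: fully concentrated after doubling
  ax <- division_angle_stats(c(rep(0, 20), rep(pi, 20)))
  expect_equal(ax$resultant_length, 1, tolerance = 1e-12)
})

test_that("apical occupancy arithmetic and the calibrated upper bound", {
  expect_equal(apical_occupancy(10, 100, 40000), 100 * pi * 25 / 40000)
  expect_equal(apical_occupancy(numeric(0), 0, 40000), 0)
  cfg <- ref_config()
  tab <- generate_stage_table(cfg, scenario("control"), n_embryos = 10,
                              seed = 51)
  occ <- vapply(tab$stages, function(stage) {
    rows <- Filter(function(m) m$stage_hpf == stage, tab$rows)
    mean(vapply(rows, function(m)
      apical_occupancy(m$mitotic_diameters, m$n_mitotic, m$apical_area),
      numeric(1)))
  }, numeric(1))
  expect_lte(max(occ), 0.20)
})

test_that("frustum volume matches limits and the slice-integration oracle", {
  expect_equal(frustum_volume(5, 2, 2), pi * 4 * 5)          # cylinder
  expect_equal(frustum_volume(5, 2, 0), pi * 4 * 5 / 3)      # cone
  expect_equal(frustum_volume(3, 2, 1), 7 * pi)
  expect_error(frustum_volume(3, 1, 2), "exceeds")
  set.seed(61)
  for (i in 1:10) {
    h <- stats::runif(1, 1, 100); R <- stats::runif(1, 1, 20)
    r <- stats::runif(1, 0, R)
    expect_equal(frustum_volume(h, R, r), frustum_volume_slices(h, R, r),
                 tolerance = 1e-9)
  }
})

test_that("trap analysis applies the cycle-capacity rule with strict inequality", {
  tr <- trap_analysis(h = 50, R = 4, r = 3, cell_density = 0.003,
                      T_CC = 6, T_M = 0.5)
  expect_equal(tr$n_max, 11)
  expect_false(tr$trap)
  # boundary equality is "at capacity", not a trap
  V <- frustum_volume(50, 4, 3)
  tr2 <- trap_analysis(50, 4, 3, cell_density = 11 / V, T_CC = 6, T_M = 0.5)
  expect_false(tr2$trap)
  expect_true(tr2$at_capacity)
  tr3 <- trap_analysis(50, 4, 3, cell_density = 11.5 / V, T_CC = 6, T_M = 0.5)
  expect_true(tr3$trap)
})

test_that("no proliferative trap at any calibrated stage", {
  cfg <- ref_config()
  tab <- generate_stage_table(cfg, scenario("control"), n_embryos = 10,
                              seed = 52)
  cal <- cfg$calibration
  cyc <- data.frame(stage_hpf = cal$stage_hpf, mean_cycle = cal$cell_cycle_mean,
                    mean_mitosis = cal$mitosis_duration)
  tb <- trap_by_stage(tab, cyc)
  expect_true(all(!tb$trap))
  expect_true(all(tb$n_measured < tb$n_max))
})
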