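test_that("generators are deterministic under a fixed seed", {
  cfg <- ref_config()
  a <- generate_stage_table(cfg, scenario("control"), n_embryos = 3, seed = 7)
  b <- generate_stage_table(cfg, scenario("control"), n_embryos = 3, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_stage_table(cfg, scenario("control"), n_embryos = 3, seed = 8)))

  p1 <- generate_mitotic_coordinates(100, seed = 5)
  p2 <- generate_mitotic_coordinates(100, seed = 5)
  expect_identical(p1$points, p2$points)
})

test_that("zero-noise generation reproduces the calibration exactly", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("stages: [20, 42]", "seed: 3",
               "calibration:",
               "  '20': {volume_cv: 0, thickness_cv: 0, cells_cv: 0, diameter_cv: 0, nuclear_zone_cv: 0, nuclear_axis_cv: 0}",
               "  '42': {volume_cv: 0, thickness_cv: 0, cells_cv: 0, diameter_cv: 0, nuclear_zone_cv: 0, nuclear_axis_cv: 0}"),
             p)
  cfg <- load_config(p)
  tab <- generate_stage_table(cfg, scenario("control"), n_embryos = 2)
  cal <- cfg$calibration
  for (m in tab$rows) {
    i <- which(cal$stage_hpf == m$stage_hpf)
    expect_equal(m$tissue_volume, cal$mean_tissue_volume[i])
    expect_equal(m$thickness_samples, rep(cal$mean_thickness[i], 5))
    expect_equal(m$n_cells, round(cal$mean_cells[i]))
    expect_equal(m$n_mitotic, round(m$n_cells * cal$mitotic_index[i]))
    expect_equal(unique(m$mitotic_diameters), cal$mean_mitotic_diameter[i])
    expect_equal(m$nuclear_zone_height, cal$nuclear_zone_height[i])
  }
})

test_that("stage-table means track the calibration within sampling error", {
  cfg <- ref_config()
  tab <- generate_stage_table(cfg, scenario("control"), n_embryos = 10, seed = 1)
  cal <- cfg$calibration
  for (stage in tab$stages) {
    rows <- Filter(function(m) m$stage_hpf == stage, tab$rows)
    V <- vapply(rows, `[[`, numeric(1), "tissue_volume")
    i <- which(cal$stage_hpf == stage)
    se <- cal$volume_cv[i] * cal$mean_tissue_volume[i] / sqrt(length(V))
    expect_lt(abs(mean(V) - cal$mean_tissue_volume[i]), 3 * se)
  }
})

test_that("hdac1 thickness samples never exceed the 55 um cap", {
  cfg <- ref_config()
  tab <- generate_stage_table(cfg, scenario("hdac1"), n_embryos = 10, seed = 2)
  th <- unlist(lapply(tab$rows, `[[`, "thickness_samples"))
  expect_true(all(th <= 55))
})

test_that("uniform cap sampling matches the closed-form colatitude CDF", {
  pts <- generate_mitotic_coordinates(
    5000, cap = list(center = c(10, -5, 3), radius = 80, theta_max = pi / 2),
    density_mode = "uniform", seed = 11)
  v <- sweep(pts$points, 2, c(10, -5, 3))
  theta <- acos(pmin(1, v[, 3] / sqrt(rowSums(v^2))))
  cdf <- function(q) (1 - cos(q)) / (1 - cos(pi / 2))
  ks <- suppressWarnings(stats::ks.test(theta, cdf))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("gradient mode rejects uniformity in equal-area azimuth bins", {
  pts <- generate_mitotic_coordinates(5000, density_mode = "gradient",
                                      seed = 12)
  phi <- atan2(pts$points[, 2], pts$points[, 1])
  counts <- table(cut(phi, seq(-pi, pi, length.out = 9)))
  expect_lt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
  expect_equal(nrow(generate_mitotic_coordinates(0, seed = 1)$points), 0)
})

test_that("cycle tracks degenerate to the mean at zero CV and keep T_M flat", {
  cal <- default_calibration()
  row <- cal[cal$stage_hpf == 30, ]
  row$cell_cycle_cv <- 0
  tr <- generate_cell_cycle_tracks(20, row, seed = 4)
  lens <- unlist(lapply(tr, function(t) {
    seg <- sort(t$events$time_hpf[t$events$event == "segregation"])
    diff(seg)
  }))
  expect_equal(lens, rep(row$cell_cycle_mean, length(lens)))
  # mitosis duration identical at every stage (flat developmental profile)
  tm <- vapply(c(20, 30, 42), function(s) {
    tr <- generate_cell_cycle_tracks(30, cal[cal$stage_hpf == s, ], seed = 5)
    cycle_lengths(tr, bin_centers = s)$mean_mitosis
  }, numeric(1))
  expect_equal(tm, rep(cal$mitosis_duration[1], 3))
})

test_that("noise-free profiles place the basal plateau at the calibrated extent", {
  for (stage in c(30, 36, 42)) {
    pr <- generate_intensity_profiles(stage, scenario("control"),
                                      n_profiles = 1, seed = 1, noise_sd = 0)
    z <- detect_basal_zone(pr$actin[[1]])
    cal <- default_calibration()
    expect_equal(z$extent_fraction,
                 cal$actin_basal_extent_fraction[cal$stage_hpf == stage],
                 tolerance = 0.01)
  }
  # control extent shrinks over development; hdac1 stays at the 30-hpf value
  e30 <- detect_basal_zone(generate_intensity_profiles(
    30, scenario("control"), 1, 1, noise_sd = 0)$actin[[1]])$extent_fraction
  e42 <- detect_basal_zone(generate_intensity_profiles(
    42, scenario("control"), 1, 1, noise_sd = 0)$actin[[1]])$extent_fraction
  h42 <- detect_basal_zone(generate_intensity_profiles(
    42, scenario("hdac1"), 1, 1, noise_sd = 0)$actin[[1]])$extent_fraction
  expect_lt(e42, e30)
  expect_equal(h42, e30, tolerance = 1e-6)
})

test_that("division angles are uniform at zero concentration and degenerate at high", {
  a <- generate_division_angles(1000, concentration = 0, seed = 6)
  C <- sum(cos(a)); S <- sum(sin(a))
  expect_lt(sqrt(C^2 + S^2) / 1000, 0.1)
  b <- generate_division_angles(50, concentration = 1e8, seed = 6,
                                mean_direction = 1)
  expect_equal(b, rep(1, 50), tolerance = 1e-3)
  # at embryo-scale n from a uniform population, the uniformity test is
  # non-significant in at least 90% of repeated samples
  ps <- vapply(1:100, function(s)
    division_angle_stats(generate_division_angles(15, 0, seed = s))$p_value,
    numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})
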