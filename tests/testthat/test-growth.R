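test_that("interphase cell volume applies the sphere formula with 10% correction", {
  expect_equal(interphase_cell_volume(10), 0.9 * pi / 6 * 1000)
  # invariant to replicating the same diameter
  expect_equal(interphase_cell_volume(rep(8.2, 7)),
               interphase_cell_volume(8.2))
  # diameter giving roughly the 20-hpf reference volume
  expect_equal(interphase_cell_volume(9.914), 459, tolerance = 1e-3)
  expect_error(interphase_cell_volume(numeric(0)), "no mitotic diameters")
})

test_that("cross-section, thickness, aspect and stacking arithmetic", {
  expect_equal(mean_cell_cross_section(40000, 100000, 1000), 50)
  expect_equal(mean_cell_cross_section(30000, 60000, 1000), 30)
  expect_equal(mean_cell_cross_section(40000, 100000, 2000), 25)
  expect_error(mean_cell_cross_section(40000, 30000, 1000), "basal")

  expect_equal(corrected_thickness(c(60, 60)), 57)
  expect_equal(corrected_thickness(c(60, 60), correct = FALSE), 60)
  expect_equal(corrected_thickness(48.4), 45.98)

  expect_equal(aspect_ratio(50, 2500), 1)
  expect_equal(aspect_ratio(55, 49), 55 / 7)
  # scale invariance: h -> k h, A -> k^2 A
  expect_equal(aspect_ratio(3 * 55, 9 * 49), aspect_ratio(55, 49))

  expect_equal(nuclear_stacking(44, 8), 5.5)
  expect_equal(nuclear_stacking(22.4, 8), 2.8)
  expect_equal(nuclear_stacking(8, 8), 1)
  expect_equal(apical_to_basal_layers(63, 8), 7.875)
})

test_that("balance residuals vanish on algebraically consistent inputs", {
  set.seed(42)
  n <- 6
  N <- cumsum(stats::runif(n, 500, 3000))
  v <- sort(stats::runif(n, 150, 450), decreasing = TRUE)
  V <- N * v
  h <- stats::runif(n, 45, 65)
  A <- V / h
  lr <- log_rate_decomposition(data.frame(
    stage_hpf = seq(20, 48, length.out = n), tissue_volume = V, n_cells = N,
    cell_volume = v, tissue_area = A, tissue_height = h))
  expect_equal(lr$residual_cells, rep(0, n), tolerance = 1e-12)
  expect_equal(lr$residual_geometry, rep(0, n), tolerance = 1e-12)
  expect_error(log_rate_decomposition(data.frame(
    stage_hpf = c(20, 20), tissue_volume = 1:2, n_cells = 1:2,
    cell_volume = 1:2, tissue_area = 1:2, tissue_height = 1:2)),
    "strictly increasing")
})

test_that("derived metrics are scale covariant in lengths", {
  tab <- tiny_stage_table()
  lam <- 1.7
  scaled <- stage_table(lapply(tab$rows, function(m) {
    m$tissue_volume <- m$tissue_volume * lam^3
    m$apical_area <- m$apical_area * lam^2
    m$total_surface_area <- m$total_surface_area * lam^2
    m$thickness_samples <- m$thickness_samples * lam
    m$mitotic_diameters <- m$mitotic_diameters * lam
    m$nuclear_zone_height <- m$nuclear_zone_height * lam
    m$nuclear_long_axis <- m$nuclear_long_axis * lam
    m
  }))
  a <- derive_cell_metrics(tab)
  b <- derive_cell_metrics(scaled)
  expect_equal(b$mean_cell_volume, a$mean_cell_volume * lam^3)
  expect_equal(b$mean_cell_cross_section, a$mean_cell_cross_section * lam^2)
  expect_equal(b$corrected_thickness, a$corrected_thickness * lam)
  expect_equal(b$cell_density, a$cell_density / lam^3)
  # aspect ratios and stacking are dimensionless
  expect_equal(b$cell_aspect_ratio, a$cell_aspect_ratio)
  expect_equal(b$tissue_aspect_ratio, a$tissue_aspect_ratio)
  expect_equal(b$nuclear_stacking, a$nuclear_stacking)
})

test_that("exponential fit recovers rate, doubling time and fold change", {
  t <- seq(20, 48, by = 4)
  V <- 5e5 * exp(0.055 * (t - 20))
  fit <- exponential_growth_fit(t, V)
  expect_equal(fit$rate, 0.055, tolerance = 1e-10)
  expect_equal(fit$doubling_time, log(2) / 0.055, tolerance = 1e-10)
  expect_equal(fit$fold_change, exp(0.055 * 28), tolerance = 1e-10)

  flat <- exponential_growth_fit(t, rep(1e6, length(t)))
  expect_equal(flat$rate, 0, tolerance = 1e-12)
  expect_true(is.na(flat$doubling_time))

  # noisy generator volumes recover the calibrated rate within 2 SE
  cfg <- ref_config()
  tab <- generate_stage_table(cfg, scenario("control"), n_embryos = 10,
                              seed = 9)
  df <- as.data.frame(tab)
  nf <- exponential_growth_fit(df$stage_hpf, df$tissue_volume_um3)
  expect_lt(abs(nf$rate - 0.055), 2 * nf$rate_se)
})

test_that("diameter-based cell volume cross-validates the count-based volume", {
  # the two independent estimators of cell volume (mitotic diameters vs
  # tissue volume / cell count) agree within 15% on calibrated fixtures
  cfg <- ref_config()
  tab <- generate_stage_table(cfg, scenario("control"), n_embryos = 10,
                              seed = 10)
  met <- derive_cell_metrics(tab)
  ratio <- met$mean_cell_volume / (met$mean_tissue_volume / met$mean_cells)
  expect_true(all(abs(ratio - 1) < 0.15))
})
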