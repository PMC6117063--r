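test_that("normalization is idempotent and affine-invariant", {
  set.seed(71)
  x <- sort(stats::runif(40))
  y <- stats::runif(40)
  p1 <- normalize_profile(x, y)
  expect_equal(min(p1$intensities), 0)
  expect_equal(max(p1$intensities), 1)
  p2 <- normalize_profile(p1$positions, p1$intensities)
  expect_equal(p2$intensities, p1$intensities, tolerance = 1e-12)
  # affine intensity transforms do not change the normalized profile
  p3 <- normalize_profile(x, 3.7 * y + 11)
  expect_equal(p3$intensities, p1$intensities, tolerance = 1e-12)
  # a linear ramp survives unchanged
  pr <- normalize_profile(seq(0, 1, length.out = 100),
                          seq(2, 5, length.out = 100))
  expect_equal(pr$intensities, seq(0, 1, length.out = 100), tolerance = 1e-12)
  expect_error(normalize_profile(x, rep(1, 40)), "constant intensity")
})

test_that("profile averaging gives pointwise mean and SEM", {
  a <- normalize_profile(seq(0, 1, length.out = 100),
                         seq(0, 1, length.out = 100))
  avg <- average_profiles(list(a, a, a))
  expect_equal(avg$intensities, a$intensities)
  expect_equal(avg$sem, rep(0, 100))
  # SEM from generator noise scales like sigma/sqrt(n)
  n <- 8
  pr <- generate_intensity_profiles(30, n_profiles = n, seed = 72)$actin
  avg2 <- average_profiles(pr)
  mid <- avg2$positions >= 0.35 & avg2$positions <= 0.65
  cal <- default_calibration()
  span <- cal$actin_apical_amp[1]  # raw dynamic range (apical peak to baseline)
  expected_sem <- cal$actin_noise_sd[1] / span / sqrt(n)
  expect_equal(mean(avg2$sem[mid]), expected_sem, tolerance = 0.5)
})

test_that("zone detection is exact on constructed ramps across extents", {
  for (extent in c(0.02, 0.08, 0.2, 0.26, 0.4, 0.6)) {
    z <- detect_basal_zone(ramp_actin_profile(extent))
    # exact up to sub-grid interpolation error (grid spacing 1/99)
    expect_lt(abs(z$extent_fraction - extent), 1.5e-3)
    expect_false(z$absent)
  }
  # micrometer conversion uses the supplied tissue height
  z26 <- detect_basal_zone(ramp_actin_profile(0.26), tissue_height = 46.15)
  expect_equal(z26$extent_um, 0.26 * 46.15, tolerance = 1e-6)
  # flat profile: no basal elevation
  flat <- normalize_profile(seq(0, 1, length.out = 100),
                            c(1, rep(0, 98), 0.01))
  zf <- detect_basal_zone(flat)
  expect_true(zf$absent)
  expect_equal(zf$extent_fraction, 0)
})

test_that("noisy averaged profiles recover the calibrated basal extents", {
  # the 42-hpf extent (8% of the axis) from 9 noisy profiles
  pr <- generate_intensity_profiles(42, n_profiles = 9, seed = 73)
  z <- detect_basal_zone(average_profiles(pr$actin))
  expect_equal(z$extent_fraction, 0.08, tolerance = 0.25)
  pr30 <- generate_intensity_profiles(30, n_profiles = 9, seed = 73)
  z30 <- detect_basal_zone(average_profiles(pr30$actin))
  expect_equal(z30$extent_fraction, 0.26, tolerance = 0.1)
})

test_that("actin zone and nuclear exclusion zone are concordant", {
  pr <- generate_intensity_profiles(30, n_profiles = 9, seed = 74)
  cc <- exclusion_zone_concordance(average_profiles(pr$actin),
                                   average_profiles(pr$nuclear))
  expect_lt(cc$correlation, -0.5)
  expect_lt(cc$boundary_gap, 0.05)
  # hdac1 at 42 hpf keeps the 30-hpf boundary, still concordant
  ph <- generate_intensity_profiles(42, scenario("hdac1"), n_profiles = 9,
                                    seed = 74)
  ch <- exclusion_zone_concordance(average_profiles(ph$actin),
                                   average_profiles(ph$nuclear))
  expect_lt(ch$boundary_gap, 0.05)
  expect_equal(ch$actin_boundary, 0.74, tolerance = 0.03)
  # rockout: no actin zone, nuclei reach the basal end
  pk <- generate_intensity_profiles(36, scenario("rockout"), n_profiles = 5,
                                    seed = 74)
  zk <- detect_basal_zone(average_profiles(pk$actin))
  expect_true(zk$absent)
  ck <- exclusion_zone_concordance(average_profiles(pk$actin),
                                   average_profiles(pk$nuclear))
  expect_true(is.na(ck$nuclear_boundary))
})

test_that("cortical ratios extract peak-height ratios per region", {
  x <- seq_len(120)
  mk <- function(amp) 0.2 + amp * pmax(0, sin(x / 4))^8
  cr <- cortical_ratios(mk(1), mk(1), mk(1))
  expect_equal(cr$basal_to_lateral, 1, tolerance = 1e-9)
  expect_equal(cr$apical_to_lateral, 1, tolerance = 1e-9)
  cr2 <- cortical_ratios(mk(1), 2 * mk(1), mk(1))
  expect_equal(cr2$basal_to_lateral, 2, tolerance = 1e-9)
  expect_error(cortical_ratios(rep(1, 50), mk(1), mk(1)), "apical")
})

test_that("control basal-to-lateral ratio rises over development; hdac1 does not", {
  get_ratios <- function(scen, stage) vapply(
    generate_region_profiles(stage, scen, n_samples = 5, seed = 75),
    function(s) cortical_ratios(s$apical, s$basal, s$lateral)$basal_to_lateral,
    numeric(1))
  c30 <- get_ratios(scenario("control"), 30)
  c42 <- get_ratios(scenario("control"), 42)
  expect_lt(stats::wilcox.test(c30, c42, alternative = "less")$p.value, 0.05)
  h30 <- get_ratios(scenario("hdac1"), 30)
  h42 <- get_ratios(scenario("hdac1"), 42)
  expect_gt(stats::wilcox.test(h30, h42)$p.value, 0.05)
})
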