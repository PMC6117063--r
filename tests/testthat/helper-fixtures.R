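# Shared fixtures, built in code at test time.

ref_config <- function() load_config()

# a small valid stage table (2 stages x 2 embryos) with hand-set numbers
tiny_stage_table <- function() {
  mk <- function(id, stage, V, ap, tot, th, n, nm, d, nz, na)
    stage_measurement(id, stage, V, ap, tot, th, n, nm, d, nz, na)
  stage_table(list(
    mk("e1", 20, 9.6e5, 22000, 40000, c(46, 47, 45, 46, 46), 2200, 30,
       c(9.7, 9.9, 9.8), 20, 8),
    mk("e2", 20, 1.0e6, 23000, 42000, c(47, 48, 46, 47, 47), 2300, 28,
       c(9.6, 9.8), 21, 8.1),
    mk("e3", 42, 3.2e6, 60000, 110000, c(60, 62, 61, 60, 61), 14500, 230,
       c(7.3, 7.5, 7.4), 44, 8),
    mk("e4", 42, 3.3e6, 61000, 112000, c(61, 63, 60, 61, 62), 15000, 240,
       c(7.2, 7.6), 43, 7.9)))
}

# a noise-free profile on the 100-point grid with a linear basal ramp whose
# half-height crossing sits exactly at 1 - extent (linear interpolation of a
# linear segment is exact, so detect_basal_zone recovers `extent` exactly)
ramp_actin_profile <- function(extent, baseline = 0.3, plateau = 0.8,
                               apical_peak = 1, half_width = 1 / 99) {
  x <- seq(0, 1, length.out = 100)
  b <- 1 - extent
  f <- pmin(pmax((x - b) / (2 * half_width) + 0.5, 0), 1)
  y <- baseline + (plateau - baseline) * f
  y[1] <- apical_peak
  normalize_profile(x, y, channel = "actin")
}

# numeric slice-integration oracle for the frustum volume
frustum_volume_slices <- function(h, R, r, n = 20000) {
  z <- (seq_len(n) - 0.5) / n * h
  rad <- R + (r - R) * z / h
  sum(pi * rad^2) * h / n
}
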