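#' Derive a reproducible child seed for a named random stream
#'
#' All stochastic functions in the package draw from streams derived from a
#' single master seed, so that modules can be re-run independently yet
#' reproducibly. The derivation is a small integer hash of the stream name
#' folded into the master seed, kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream character stream name (e.g. `"stage_table"`).
#' @return An integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 1000000007
  as.integer(((abs(seed) %% 65536) * 32749 + h) %% 2147483647)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle against a unimodal alternative, using the mean resultant length
#' with the standard small-sample correction for the p-value.
#'
#' @param angles numeric vector of angles in radians.
#' @return A list with `r` (mean resultant length), `statistic` (Z = n r^2)
#'   and `p.value`.
#' @export
rayleigh_test <- function(angles) {
  stopifnot(is.numeric(angles), length(angles) >= 1)
  n <- length(angles)
  C <- sum(cos(angles)); S <- sum(sin(angles))
  r <- sqrt(C^2 + S^2) / n
  Z <- n * r^2
  # Zar (1999) correction, accurate for small n
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(r = r, statistic = Z, p.value = max(0, min(1, p)))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the circular uniform
#' distribution on `[0, 2*pi)`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  if (kappa > 1e6) return(rep((mu %% (2 * pi)), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r0 * z) / (r0 + z)
    cc <- kappa * (r0 - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Find local maxima with a prominence floor
#'
#' Local maxima whose prominence (height above the higher of the two
#' bounding minima that separate the peak from higher terrain) is at least
#' `min_prominence`.
#'
#' @param x numeric signal.
#' @param min_prominence minimum prominence; peaks below it are dropped.
#' @return data.frame with columns `index`, `height`, `prominence`.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(0), height = numeric(0),
                               prominence = numeric(0)))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(idx)) return(data.frame(index = integer(0), height = numeric(0),
                                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- x[i]
    # walk left until terrain exceeds the peak (or edge), track the minimum
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(x[1:i])
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
    if (j > n) rmin <- min(x[i:n])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = idx[keep], height = x[idx[keep]], prominence = prom[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
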