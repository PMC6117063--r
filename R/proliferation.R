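#' Cell-cycle statistics from lineage tracks
#'
#' Cycle length is the interval between consecutive chromosome-segregation
#' events of a track; each cycle is assigned to the stage bin whose center
#' is nearest its midpoint and within the bin half-width (+/- 3 h by
#' convention). Mitosis duration is segregation time minus the immediately
#' preceding rounding time. Tracks with fewer than two segregations
#' contribute only to the mitosis-duration estimate.
#'
#' @param tracks a `lineage_tracks` object (see
#'   [generate_cell_cycle_tracks()]) or a bare list with the same shape.
#' @param bin_centers stage bin centers, hpf.
#' @param half_width bin half-width, h (default 3).
#' @return data.frame with one row per non-empty bin: `stage_hpf`,
#'   `mean_cycle`, `cov_cycle`, `mean_mitosis`, `n_cycles`.
#' @export
cycle_lengths <- function(tracks, bin_centers = c(20, 24, 30, 36, 42, 48),
                          half_width = 3) {
  cycles <- data.frame(mid = numeric(0), len = numeric(0))
  tm <- numeric(0)
  for (tr in tracks) {
    ev <- tr$events
    seg <- sort(ev$time_hpf[ev$event == "segregation"])
    rnd <- sort(ev$time_hpf[ev$event == "rounding"])
    for (s in seg) {
      prev <- rnd[rnd < s]
      if (length(prev)) tm <- c(tm, s - max(prev))
    }
    if (length(seg) >= 2) {
      len <- diff(seg)
      mid <- utils::head(seg, -1) + len / 2
      cycles <- rbind(cycles, data.frame(mid = mid, len = len))
    }
  }
  out <- lapply(bin_centers, function(b) {
    # nearest-bin assignment inside the half-width window
    near <- vapply(cycles$mid, function(m)
      abs(m - b) <= half_width && b == bin_centers[which.min(abs(bin_centers - m))],
      logical(1))
    if (!any(near)) return(NULL)
    len <- cycles$len[near]
    data.frame(stage_hpf = b, mean_cycle = mean(len),
               cov_cycle = if (length(len) > 1) stats::sd(len) / mean(len) else 0,
               mean_mitosis = if (length(tm)) mean(tm) else NA_real_,
               n_cycles = length(len))
  })
  do.call(rbind, out)
}

#' Mitotic index
#'
#' Fraction of all cells that are in mitosis.
#'
#' @param n_mitotic mitotic cell count.
#' @param n_cells total cell count (> 0).
#' @return Fraction in [0, 1].
#' @export
mitotic_index <- function(n_mitotic, n_cells) {
  stopifnot(all(n_cells > 0), all(n_mitotic >= 0), all(n_mitotic <= n_cells))
  n_mitotic / n_cells
}

#' Parameters of the progenitor division/differentiation model
#'
#' Progenitors divide at a constant rate `k` (division events per
#' progenitor per hour). Each division yields 2 progenitors with
#' probability `p`, 2 committed precursors/neurons with probability
#' `(1-p)*alpha`, and 1 of each with probability `(1-p)*(1-alpha)`. Before
#' `t_transition` all divisions are proliferative (`p = 1`); after it `p`
#' takes the supplied value. Defaults: `k = 0.11`/h, 35% differentiating
#' divisions after 35 hpf (`p = 0.65`), only symmetric differentiation
#' (`alpha = 1`), 2,177 progenitors at 20 hpf.
#'
#' @param k division rate, 1/h.
#' @param p post-transition probability of a proliferative division.
#' @param alpha probability a differentiating division is symmetric.
#' @param t_transition transition time, hpf.
#' @param N0 initial progenitor count.
#' @param t0 initial time, hpf.
#' @return List of class `growth_model_params`.
#' @export
growth_model_params <- function(k = 0.11, p = 0.65, alpha = 1,
                                t_transition = 35, N0 = 2177, t0 = 20) {
  stopifnot(k >= 0, p >= 0, p <= 1, alpha >= 0, alpha <= 1, N0 > 0,
            t_transition >= t0)
  structure(list(k = k, p = p, alpha = alpha, t_transition = t_transition,
                 N0 = N0, t0 = t0), class = "growth_model_params")
}

#' Mean-field trajectories of the division/differentiation model
#'
#' Deterministic solution of the branching rules: progenitors P obey
#' `dP/dt = k (2p - 1) P` and committed cells obey
#' `dNeu/dt = 2 k (1-p) alpha P + k (1-p)(1-alpha) P`, with `p = 1` before
#' the transition time. Both phases have closed forms (exponentials), which
#' are used directly.
#'
#' @param params a [growth_model_params()].
#' @param t_grid times (hpf), within `[t0, 48]` by convention but any
#'   `t >= t0` is accepted.
#' @return data.frame with columns `t`, `progenitors`, `neurons`, `total`.
#' @export
simulate_growth_model <- function(params, t_grid = seq(20, 48, by = 0.5)) {
  stopifnot(inherits(params, "growth_model_params"), all(t_grid >= params$t0))
  k <- params$k; p <- params$p; a <- params$alpha
  tt <- params$t_transition
  P_tt <- params$N0 * exp(k * (tt - params$t0))
  lam <- k * (2 * p - 1)                       # post-transition progenitor rate
  nu <- k * (1 - p) * (2 * a + (1 - a))        # committed production per progenitor
  P <- ifelse(t_grid <= tt,
              params$N0 * exp(k * (t_grid - params$t0)),
              P_tt * exp(lam * (t_grid - tt)))
  # integrate nu * P over (tt, t] in closed form
  Neu <- ifelse(t_grid <= tt, 0,
                if (abs(lam) > 1e-12) {
                  nu / lam * P_tt * (exp(lam * (pmax(t_grid, tt) - tt)) - 1)
                } else {
                  nu * P_tt * (pmax(t_grid, tt) - tt)
                })
  data.frame(t = t_grid, progenitors = P, neurons = Neu, total = P + Neu)
}

#' Counterfactual pure-proliferation count
#'
#' Cell count after `delta_t` hours if every cell keeps dividing at rate
#' `k`: `N0 * exp(k * delta_t)`.
#'
#' @param N0 initial count.
#' @param k division rate, 1/h.
#' @param delta_t elapsed time, h (>= 0).
#' @return Expected count.
#' @export
pure_proliferation_count <- function(N0, k, delta_t) {
  stopifnot(delta_t >= 0, N0 > 0, k >= 0)
  N0 * exp(k * delta_t)
}

#' Absolute differentiated-cell counts from relative fractions
#'
#' Multiplies FACS-style relative fractions per cell type by the total cell
#' count.
#'
#' @param fractions named numeric vector of fractions in [0, 1], summing to
#'   at most 1.
#' @param total_cells total cell count.
#' @return Named numeric vector of absolute counts.
#' @export
absolute_neuron_counts <- function(fractions, total_cells) {
  stopifnot(all(fractions >= 0), all(fractions <= 1), total_cells >= 0)
  if (sum(fractions) > 1 + 1e-12)
    stop("fractions sum to more than 1")
  fractions * total_cells
}

#' Stochastic agent-based realization of the division/differentiation rules
#'
#' Gillespie-style simulation with exponential waiting times: each
#' progenitor divides at rate `k`; the division outcome follows the
#' (p, alpha) fate probabilities (with `p = 1` before the transition).
#' Used as an independent check that the mean-field solution matches the
#' average behaviour of the stochastic rules; the memoryless waiting times
#' validate the mean-field mathematics, not the gamma-like biology of real
#' cycles.
#'
#' @param params a [growth_model_params()].
#' @param t_end end time, hpf.
#' @param seed integer seed.
#' @return List with final `progenitors`, `neurons`, `total`.
#' @export
simulate_growth_agents <- function(params, t_end = 48, seed = 1) {
  stopifnot(inherits(params, "growth_model_params"))
  set.seed(child_seed(seed, "agents"))
  t <- params$t0
  P <- round(params$N0); Neu <- 0
  while (t < t_end && P > 0) {
    rate <- params$k * P
    t <- t + stats::rexp(1, rate)
    if (t >= t_end) break
    p_eff <- if (t <= params$t_transition) 1 else params$p
    u <- stats::runif(1)
    if (u < p_eff) {
      P <- P + 1
    } else if (u < p_eff + (1 - p_eff) * params$alpha) {
      P <- P - 1; Neu <- Neu + 2
    } else {
      Neu <- Neu + 1
    }
  }
  list(progenitors = P, neurons = Neu, total = P + Neu)
}
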