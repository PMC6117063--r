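---
title: "Decomposing isotropic growth of a pseudostratified neuroepithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing isotropic growth of a pseudostratified neuroepithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psegrowth)
```

## The problem

Between 20 and 48 hours post fertilization (hpf) the zebrafish retinal
neuroepithelium — a pseudostratified epithelium (PSE) in which every cell
spans the apicobasal axis and all mitoses happen at the apical surface —
grows several-fold in volume while keeping its overall shape. `psegrowth`
decomposes that growth into cell-level contributions: how much comes from
cell number, how much from cell volume, how much from area expansion versus
thickening, and which cellular mechanisms (apical crowding, nuclear
packing, actin redistribution, tension balance) permit or constrain it.

The package operates on per-embryo, per-stage morphometric tables
(tissue volume, apical/total surface area, thickness samples, cell and
mitotic counts, mitotic diameters, nuclear-zone geometry), 3D mitotic
coordinates, lineage-track event times, and apicobasal intensity profiles.
Because the original measurements derive from manually segmented light-sheet
stacks, the package ships a calibrated synthetic generator that emulates
their statistical structure, so every analysis stage is testable end to end.

## Growth-rate balance

For stage means of tissue volume $V$, cell number $N$, cell volume $v$,
tissue area $A$ and height $h$, two identities hold by definition:
$V = N\,v$ and $V = A\,h$. On cumulative logarithmic rates this becomes
additive: $\Delta\ln V = \Delta\ln N + \Delta\ln v$ and
$\Delta\ln V = \Delta\ln A + \Delta\ln h$. `log_rate_decomposition()`
accumulates $\ln(Q_{i+1}/Q_i)$ per interval and reports the balance
residuals, which vanish identically on algebraically consistent inputs and
should stay within the pooled embryo-level SD band (delta method,
`pooled_rate_sd()`) on measured or generated data. Because quantities are
measured independently (segmentation for $V$, spot counts for $N$,
mitotic-diameter spheres for $v$), the residual is a genuine consistency
diagnostic, not a tautology.

Aspect ratios are height over the square root of area
(`aspect_ratio()`), at cell scale (mean cross-sectional endfoot area) and
tissue scale; constancy of the tissue ratio is the operational definition
of isotropic growth.

Cell-level metrics use three stated corrections: the mean of five
thickness samples is reduced by 5% for the thinner ciliary marginal zone
(`corrected_thickness()`, toggleable); mitotic sphere volumes are reduced
by 10% to represent interphase cells (`interphase_cell_volume()`); basal
tissue area is total minus apical area.

## Proliferation model

Cycle lengths come from lineage tracks as inter-segregation intervals,
binned by cycle midpoint into stage ± 3 h bins; mitosis duration is
segregation minus rounding time (`cycle_lengths()`). The fate model
(`simulate_growth_model()`) is a mean-field branching process: progenitors
divide at constant rate $k$; each division yields two progenitors with
probability $p$, two committed cells with probability $(1-p)\alpha$, one of
each with probability $(1-p)(1-\alpha)$; $p = 1$ before the transition
time. Defaults are $k = 0.11$/h, $p = 0.65$ after 35 hpf, $\alpha = 1$,
2,177 progenitors at 20 hpf. $k$ is the instantaneous exponential event
rate: that reading reproduces the counterfactual of ~47,000 cells at
48 hpf from 2,177 at 20 hpf under pure proliferation
(`pure_proliferation_count()`). A Gillespie agent-based realization of the
same rules (`simulate_growth_agents()`) serves as an independent check of
the closed-form solution; its exponential waiting times validate the
mean-field mathematics, not the gamma-like dispersion of real cycles.
With the published parameters the mean-field total at 48 hpf exceeds the
measured ~18,000 cells; the model exposes its parameters so stage-varying
rates can be explored, but the package does not guess an unpublished
parameterization.

## Apical surface statistics

Mitotic coordinates are referred to a least-squares sphere
(`fit_sphere()`, linear Coope formulation) and projected by the Lambert
azimuthal equal-area mapping $\rho = 2R\sin(\theta/2)$
(`project_equal_area()`); the projection pole is taken from the sphere
center through the point centroid, since no pole convention is implied by
the data. Equal solid-angle patches map to equal planar areas (exactly, by
the Jacobian identity checked in the tests), so planar binned densities
(`density_heatmap()`) are faithful per-area densities; uniformity is
tested on equal-area annuli (`annulus_uniformity_test()`). Division angles
are axial data (a division axis has no sign), so angles are doubled before
the Rayleigh test (`division_angle_stats()`); the default rose sector is
10 degrees.

The "proliferative trap" hypothesis asks whether apical area limits
proliferation. Two tests: (i) apical occupancy — mitotic count times mean
mitotic cross-section over apical area (`apical_occupancy()`); (ii) the
mitotic frustum — the truncated cone under one mitotic cell,
$V = \tfrac{\pi}{3}h(R^2 + r^2 + Rr)$ (`frustum_volume()`), holds
$n = \rho_{cell} V$ cells, which must satisfy
$n \le (T_{CC} - T_M)/T_M$ for all of them to reach the apical surface in
turn (`trap_analysis()`). The trap verdict uses strict inequality;
equality is reported as "at capacity".

## Apicobasal intensity profiles

Profiles are resampled to a 100-point grid with min-max intensity
normalization (`normalize_profile()`; 0 = apical). The basal actin
accumulation is called by a half-height rule (`detect_basal_zone()`): the
boundary is the interpolated position where the contiguous basal region
first exceeds baseline plus half the plateau elevation. The baseline is
the lower quartile of the axis interior (positions 0.15–0.95) and the
plateau the mean of the two highest basal-30% intensities; these robust
estimators keep the call exact (to sub-grid interpolation error,
< 0.0015 of the axis) for plateau extents from 2% to 60% of the axis,
which fixed central/basal windows cannot do. A profile whose basal
elevation is below 10% of the normalized range is called "absent".
Concordance with the nuclear exclusion zone is quantified by the Pearson
correlation over the basal 30% and the actin-vs-nuclear boundary gap
(`exclusion_zone_concordance()`). Cortical ratios extract local maxima
with prominence at least 10% of the region range (the original analysis
used an unspecified peak finder) and compare mean peak heights
basal/lateral and apical/lateral (`cortical_ratios()`).

## Tension-balance cell shape

Cells are truncated cones with apical and basal line tensions
$\Lambda_a, \Lambda_b$ on the two perimeters and lateral surface tension
$T_l$ on the lateral face. The energy
$E = 2\pi r_a \Lambda_a + 2\pi r_b \Lambda_b +
T_l\,\pi(r_a + r_b)\sqrt{h^2 + (r_b - r_a)^2}$
is the minimal functional consistent with that tension assignment; it is
this package's modelling choice. Minimization at fixed volume
(`cell_shape_from_tensions()`; bounded scalar search over the basal radius
under the measured constant apical-to-basal area-ratio constraint,
objective tolerance $10^{-10}$) sets the shape. Under the cylinder
constraint ($r_a = r_b$) the problem collapses to
$E(r) = 2\pi r(\Lambda_a + \Lambda_b) + 2 T_l V / r$, minimized at
$h = (\Lambda_a + \Lambda_b)/T_l$ independent of volume — derived here and
used as the internal oracle for the numerical minimizer.

A `tension_schedule()` drives development: the ratio
$(\Lambda_a + \Lambda_b)/T_l$ is constant before the transition
(default 35.5 hpf, the midpoint of the observed 35–36 hpf window), ramps
linearly over 6 h, and plateaus. `calibrate_schedule()` inverts the solver
so the solved height matches reference heights. In the control scenario
the pre-transition plateau matches the 30-hpf height (55 um) and the
post-transition plateau is calibrated so the tissue aspect ratio returns
to its starting value at 48 hpf — the package's formalization of
"redistribution-driven elongation restores isotropy". In the
no-redistribution (hdac1-like) scenario the schedule stays constant, so
the height never exceeds the 30-hpf value and the aspect ratio decreases
monotonically as area grows. Trajectory drift (`aspect_drift()`) is the
net endpoint change $|ar_{end} - ar_{start}|/ar_{start}$: under a
pre-transition-constant schedule with exponential volume growth the ratio
necessarily dips transiently before the transition (as it does in the
measurements, where height lags area growth before 36 hpf), so a max/min
criterion would conflate that transient with the endpoint behaviour the
scenarios distinguish.

## The synthetic generator and what passing tests mean

`default_calibration()` fixes one stage table of generator means:

* tissue volume exponential at 0.055/h (doubling time $\ln 2 / 0.055
  \approx 12.6$ h), lognormal multiplicative noise, CV 0.12;
* cell number exponential through 2,177 (20 hpf) and 18,000 (48 hpf),
  embryo-level CV 0.10 plus Poisson sampling;
* cell volume derived as $V/N$ (441 → 249 um^3), and mitotic diameters
  back-computed so the diameter estimator recovers it. The published
  endpoint trio (volume ×4.4, cells ×8, cell volume 440 → 140 um^3) is
  mutually inconsistent as printed (8 × 140/440 ≈ 2.6 ≠ 4.4), so the
  generator preserves the volume law and the cell-count anchors and lets
  cell volume follow; only its 20-hpf value (441 ≈ 440 um^3) is treated
  as a recovery target. This choice makes the balance identities hold at
  the level of calibration means, which the balance tests require;
* thickness in the 46–63 um band (55 um at 30 hpf), CV 0.05; apical to
  basal area ratio constant at 1.3;
* mitotic index 1.0–1.6% with a mid-development peak — not printed in the
  source text, it is calibrated forward from the hard observation that
  mitotic cells never occupy more than 20% of the apical surface, giving
  implied stage-mean occupancies of 8–17%;
* gamma cell cycles, 7.3 h (30 hpf) to 5.3 h (42 hpf) with CoV falling
  0.28 → 0.12; mitosis 0.42 h (25 min) at every stage — a typical rounded
  mitosis duration, flat across development;
* actin plateau extents 28/27/26/20/8/5% of the axis over the six stages;
  plateau edges are sharp logistics (width 0.004 of the axis), amplitudes
  0.9 (apical peak), 0.45 (plateau) over a 0.25 baseline, noise SD 0.04;
* nuclear zone height giving stacking 2.5 → 7.2 nuclei over an 8-um
  nuclear long axis (5.5 at 42 hpf).

Embryo-level CVs are package choices: the source reports figure error bars
but not embryo-level variance. Scenarios: `hdac1` freezes the actin extent
at its 30-hpf value and caps thickness at 55 um with proliferation
unchanged; `rockout` removes the plateau and suppresses proliferation
after onset; `hua` only blocks proliferation.

What the generator does *not* emulate: spatial correlation between
neighboring measurements, non-spherical (ellipsoidal or cup-rim) apical
geometry, interkinetic nuclear migration dynamics per nucleus, segmentation
bias, or stage-dependent measurement error. Passing recovery tests
therefore demonstrate that the estimators are correct and well-calibrated
under realistic noise levels — not that they are robust to every artifact
of real light-sheet data.

## Numerical choices and problem sizes

Seeds flow from a single master seed through named child streams
(`child_seed()`), so modules are independently reproducible. Degenerate
inputs are rejected loudly: coplanar sphere fits, constant-intensity
profiles, apical area at least the total area, fraction sums above 1.
Antipodal projection points are flagged rather than dropped. The trap
verdict at the capacity boundary is "no trap, at capacity". Test and
acceptance runs use 10 embryos per stage (the study's own per-stage n),
254 lineage tracks (likewise), 9 profiles per stage, and 5,000-point
samples for distributional checks — sizes at which every stochastic
tolerance in the tests has comfortable power on a single CPU.

## Known limitations

* The mean-field fate model with published parameters overshoots measured
  48-hpf counts; resolving this would require unpublished stage-varying
  rates.
* The tension model is quasi-static and single-cell; no vertex model, no
  buckling or fold prediction (the folded hdac1 morphology is outside the
  simplified description).
* The equal-area projection assumes a spherical apical surface; strongly
  aspherical retinas would need an ellipsoidal reference.
* Zone detection assumes a single contiguous basal plateau; multi-modal
  basal signal would be called at its most apical half-height crossing.

## Worked example

```{r example, eval = FALSE}
cfg <- load_config()                      # packaged reference configuration
rep <- run_pipeline(cfg, scenario("control"), seed = 1)
rep$growth_fit$rate                       # ~0.055/h
max(rep$occupancy$occupancy)              # < 0.20
any(rep$trap$trap)                        # FALSE: no proliferative trap
rep$zones$extent_fraction                 # 0.28 ... 0.05 over the six stages
rep$mechanics$aspect_constant             # TRUE (control), FALSE for hdac1
```
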