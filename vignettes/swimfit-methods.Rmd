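---
title: "Swimming economy, exercise growth and muscle marker expression with swimfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swimming economy, exercise growth and muscle marker expression with swimfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimfit)
```

## Scope

`swimfit` implements the analysis chain of a swim-tunnel exercise-physiology
experiment on small fish (the defaults are tuned to adult zebrafish in
1.8 L Blazka-style respirometers): closed respirometry to mass-specific
oxygen uptake, critical swimming speed from stepped-velocity trials,
quadratic metabolic modelling with SMR extrapolation and cost-of-transport
optimisation, a pre/post growth-comparison test battery for
exercised-vs-resting cohorts, and relative quantification of muscle growth
marker genes from triplicate qPCR Ct plates. A seeded synthetic-data
generator produces every input with known ground truth, so the whole
pipeline can be exercised and validated without laboratory data.

## Respirometry

During a closed phase the tunnel's water inlet is shut and dissolved oxygen
falls linearly while the fish respires. Readings are percent air saturation
from a two-point calibrated electrode, sampled every 2 s. Conversion to
concentration uses the Benson & Krause (1984) solubility relation (as in the
USGS/APHA tables), parameterised by temperature, salinity and barometric
pressure; at 28 °C in fresh water at 1 atm the saturation concentration is
244.6 µmol L⁻¹. The uptake rate is

$$\dot M_{O_2} = \frac{|\Delta[O_2]/\Delta t| \cdot V}{M}$$

with the slope estimated by ordinary least squares over the closed phase
(units µmol L⁻¹ h⁻¹), $V$ the tunnel volume in litres and $M$ the body mass
in grams. Options that matter:

* `min_r_squared` (default 0.9): declines with a poorer linear fit are
  flagged, not discarded — at low speeds and short closed phases the drop in
  oxygen is small relative to sensor noise and a weak r² is expected rather
  than pathological.
* leading/trailing `trim` (s, default 0): discards mixing transients.
* `blank_slope` (default off): optional background-respiration subtraction.
  No electrode-drift or blank correction is applied by default, and reports
  flag when one is; the default pipeline therefore assumes a clean, drifting
  -free electrode.

## Critical swimming speed

Stepped-velocity trials increase speed by $U_{ii}$ = 0.05 m s⁻¹ every
$T_{ii}$ = 600 s until the fish can no longer hold station. The Brett
interpolation

$$U_{crit} = U_i + \frac{T_i}{T_{ii}} U_{ii}$$

uses the highest fully maintained speed $U_i$ and the time swum into the
fatigue interval $T_i$. Protocols that fatigue each fish repeatedly are
supported; the default estimate uses the first fatigue event, with
`event = "mean"` averaging all events — measured fish fatigue three times in
the reference protocol and the two choices agree for a well-rested fish.
Relative speeds are always expressed in *standard* body lengths per second
(BL s⁻¹), never total length.

## Metabolic model and cost of transport

Oxygen uptake at 25, 50, 75 and 100 %U_crit is fitted by least squares to

$$\dot V_{O_2}(U) = \mathrm{SMR} + aU^2 + bU,$$

a free-intercept quadratic whose intercept extrapolates the standard
metabolic rate at zero swimming speed. The routine metabolic rate (RMR) is
defined operationally as the measured uptake at the 5 %U_crit minimal-flow
condition; it is carried as a datum and excluded from the curve fit. Cost of
transport divides uptake by speed, and the optimal swimming speed is the
vertex of the quadratic COT curve, $U_{opt} = -b_2/(2a_2)$, where the first
derivative vanishes — an upward parabola ($a_2 > 0$) is required, otherwise
`find_uopt()` refuses.

Two deliberate unit/axis conventions:

* **Speed axis.** The default axis is %U_crit. Group curves of this kind are
  only self-consistent on that axis (e.g. a fitted curve with SMR ≈ 43.8 and
  coefficients (0.0081, −0.4353) predicts ≈ 81 µmol g⁻¹ h⁻¹ at $U = 100$,
  matching the observed maximum uptake); absolute cm s⁻¹ is available via
  `speed_axis = "cm_s"`, with conversions always through the fish's own
  U_crit.
* **COT scale.** `cot_from_vo2()` reports either strict µmol g⁻¹ m⁻¹
  (speed in cm s⁻¹ → metres per hour) or the plain ratio $\dot V_{O_2}/U$ on
  the chosen axis ("curve" scale), which is the scale on which group COT
  polynomials are conventionally printed and minimised. Both are carried in
  `swim_fitness()` output, clearly labelled, because the two scales are not
  interconvertible without fixing the axis convention.
* COT is never extrapolated below the lowest measured speed for reporting:
  the ratio diverges as $U \to 0$.

Per-fish-first policy: curves are fitted per fish and the derived quantities
(SMR, U_opt, COT_opt …) averaged across fish as mean ± SEM; a pooled
group-curve mode fits one curve to all points. The two disagree slightly by
construction — the vertex of the mean curve is not the mean of the vertices —
and both are reported.

## Growth statistics

The comparison battery mirrors standard practice for training experiments:
Kolmogorov–Smirnov normality screening first (advisory; one-sample KS
against a normal with the sample moments, which is conservative when the
parameters are estimated), then Student t-tests: unpaired two-tailed at
baseline (groups should not differ before training), paired one-tailed
within each group (pre vs post), and unpaired one-tailed between groups
after training. The one-tailed direction is part of the comparison
specification and never inferred from the data (the hypotheses here:
swimmers grow, resters lose weight). The unpaired default is the classical
pooled-variance Student test; Welch is available by flag. Percent
differences are $100(A - B)/B$ with $B$ the reference group mean, computed
from the package's own inputs.

## qPCR relative quantification

Triplicate wells are averaged, with a QC flag when the replicate SD exceeds
0.5 cycles. ΔCt normalises each target against the same-fish rps18 mean Ct
*within the same primer set* — the assay uses different rps18 primer pairs
for its two gene panels, and cross-set normalisation is refused. Fold
changes follow Livak's 2^−ΔΔCt with each swimmer referenced to the rester
group mean ΔCt, reported as the arithmetic mean ± SEM of the per-fish fold
changes (a geometric mean is also returned; amplification efficiency is
fixed at 2.0 by default, with an efficiency-corrected base available when
standard-curve efficiencies exist). Group differences use two-sided
Mann–Whitney U tests, exact for combined n ≤ 20 without ties. Outlier
screening uses the iterative two-sided Grubbs test at α = 0.05 — the
conventional small-sample choice — capped at 2 removals per gene per group;
every removal is logged. A guard test flags datasets whose rps18 mean Ct
differs between groups, which would invalidate the normalisation.

Note a small-sample property of the arithmetic-mean Livak estimator: because
$2^{-x}$ is convex, technical Ct noise inflates the expected mean fold
change slightly (about +0.7 % at triplicate noise SD 0.2 cycles with n = 8
per group). The geometric mean does not share this bias; the arithmetic
mean remains the default because it matches how fold changes of this assay
are conventionally reported.

## Synthetic data

The generators emulate: linear closed-phase O₂ declines from 100 %AS with
i.i.d. Gaussian sensor noise at 2-s sampling; a quadratic uptake–speed law
(defaults SMR 43.79 µmol g⁻¹ h⁻¹, a = 0.0081, b = −0.4353 on the %U_crit
axis); fatigue at a true U_crit of 0.548 m s⁻¹ under the 0.05 m s⁻¹ / 600 s
protocol, exact by construction in the noiseless case and with optional
Gaussian fatigue-time jitter that may spill into adjacent intervals; cohort
growth with group-specific change distributions (swimmers +0.18 cm TL and
+0.10 g BW, resters stable length and −0.07 g BW, individual baseline SDs
0.18 cm and 0.09 g — chosen so that group SEMs at n ≈ 80 match the reported
precision); and Ct plates with a stable housekeeping gene (Ct 18), per-gene
rester ΔCt baselines and swimmer ΔCt shifted by −log₂ of the true fold
change, with replicate noise SD 0.2 cycles. Default trace noise is 0.5 %AS.

A single root seed fans out to per-fish streams by stable hashing of the
fish id, so adding a fish never perturbs the others' data and every output
is a deterministic function of (truth, seed).

What the generators do *not* emulate — and what passing recovery tests
therefore cannot show about real data: electrode drift and non-linear sensor
error, spontaneous activity bursts during closed phases, biological
between-fish variation in the metabolic curve parameters, amplification
efficiencies different from 2.0, non-Gaussian Ct error, and any behavioural
structure (burst-and-glide kinematics, schooling).

## Numerical choices and degenerate inputs

* Quadratic fits require ≥ 3 distinct speeds; exact interpolation returns
  r² = 1 (guarded against 0/0 for constant responses).
* A fitted decline slope that is numerically zero-positive (flat trace) is
  treated as zero consumption; a genuinely positive slope is an error unless
  overridden.
* Paired growth tests with all-zero differences return t = 0, one-tailed
  p = 0.5 rather than erroring.
* `find_uopt()` agrees with a 10⁻³-step grid search to < 10⁻²; tests pin
  this.
* Grubbs critical values come from the closed-form t-distribution
  expression; n < 4 skips screening with a warning.
* Test-suite problem sizes (e.g. 10 synthetic fish, cohorts of 10–78 per
  group, 500 Monte-Carlo replicates for fold-change recovery) were chosen as
  the smallest sizes at which the recovery checks are statistically
  meaningful.

## Known limitations

* The strict µmol g⁻¹ m⁻¹ COT and the curve-scale COT differ by the axis
  convention; published group polynomials on the %U_crit axis cannot be
  converted to strict per-metre units without the per-fish U_crit values.
* SMR extrapolation inherits the quadratic form; at speeds below the lowest
  measurement it is a model statement, not a measurement.
* The Mann–Whitney normal approximation (used with ties or combined n > 20)
  is asymptotic; exact enumeration covers the study-sized groups.
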