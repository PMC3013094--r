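# swimfit

Swim-tunnel respirometry, swimming economy, exercise-induced growth and
muscle-marker qPCR analysis for small fish, with a seeded synthetic-data
generator for end-to-end validation.

## What it computes

Exercise-physiology experiments on fish in Blazka-style swim tunnels produce
four kinds of data, and `swimfit` covers the full chain from raw records to
group statistics:

1. **Respirometry.** During a closed phase, dissolved oxygen (recorded in %
   air saturation every 2 s) falls linearly as the fish respires. Readings
   are converted to µmol L⁻¹ with the Benson–Krause solubility relation and
   the uptake rate is

   ṀO₂ = |Δ[O₂]/Δt| · V / M   (µmol O₂ g⁻¹ h⁻¹),

   with V the tunnel volume (L) and M the body mass (g).

2. **Critical swimming speed.** Stepped-velocity trials (increments U_ii =
   0.05 m s⁻¹ every T_ii = 600 s) end at fatigue; the Brett interpolation
   gives U_crit = U_i + (T_i/T_ii)·U_ii. Speeds convert to standard body
   lengths per second via the fish's standard BL.

3. **Swimming economy.** Uptake at 25–100 %U_crit is fitted to
   V̇O₂ = SMR + aU² + bU (free intercept = extrapolated standard metabolic
   rate). Cost of transport COT = V̇O₂/U is fitted by a second quadratic
   whose vertex U_opt = −b₂/(2a₂) is the energetically optimal swimming
   speed, with COT_opt the curve value there.

4. **Growth and expression.** Pre/post morphometrics of exercised vs resting
   cohorts run through a KS-screened Student t-test battery with percent
   differences; triplicate qPCR Ct plates run through rps18 ΔCt
   normalisation, Grubbs outlier screening, Livak 2^−ΔΔCt fold changes and
   two-sided Mann–Whitney U tests.

A generator module (`synthetic_truth()`, `simulate_o2_trace()`,
`simulate_ucrit_trial()`, `simulate_cohort()`, `simulate_ct_table()`,
`write_synthetic_inputs()`) emits every input dialect with known ground
truth, deterministically per seed, so each stage's recovery can be tested.

## Worked example

```r
library(swimfit)

truth <- synthetic_truth(seed = 42)                  # study-condition defaults
paths <- write_synthetic_inputs(truth, "demo")       # traces/trials/cohort/Ct CSVs
cfg <- run_config(traces = paths$traces, trials = paths$trials,
                  cohort = paths$cohort, ct = paths$ct,
                  out_dir = "demo/out", seed = 42)
res <- run_pipeline(cfg)
```

`demo/out/summary.txt` then contains (abridged):

```
Swimming economy (per-fish means +/- SEM, n = 10):
  ucrit_ms            0.548 +/- 0
  ucrit_bls           17.82 +/- 0.267
  smr                 43.92 +/- 3.24
  vo2max              80.81 +/- 0.922
  uopt_pct            77.77 +/- 0.575
  uopt_ms            0.4262 +/- 0.00315

Growth comparisons:
  swimmer_bw   body_weight_g  t =  24.850, p = 3.15e-40, diff +22.9%
  rester_bw    body_weight_g  t = -18.265, p = 3.35e-30, diff -17.2%
  post_bw      body_weight_g  t =  10.684, p = 9.47e-21, diff +49.1%

qPCR fold changes (swimmers over resters):
  ghrb    fc  0.56 +/- 0.01  p = 0.000155 *
  myhz2   fc  8.64 +/- 0.47  p = 0.000155 *
  mstnb   fc  5.44 +/- 0.27  p = 0.000155 *
```

Reading it: every fish's U_crit is recovered exactly from its noiseless
fatigue trial (0.548 m s⁻¹, ≈ 17.8 BL s⁻¹ for these body lengths); the
extrapolated SMR (43.9 µmol g⁻¹ h⁻¹) matches the generating curve's
intercept within noise; the optimal speed sits near 78 %U_crit (the vertex
of the generating quadratic); swimmers gained and resters lost body weight
with decisive paired and between-group tests; and the fold changes recover
the generator's true per-gene values (e.g. ghrb down-regulated, myhz2 and
mstnb strongly up-regulated), with Mann–Whitney significance stars.

The methods vignette (`vignettes/swimfit-methods.Rmd`) documents the models,
unit conventions, QC thresholds and the generator's assumptions.

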