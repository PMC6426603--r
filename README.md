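# swarmotility

Swarming *Escherichia coli* cells remodel their chemotaxis physiology: cells
taken from the edge of a swarm and observed in liquid tumble far less
(median tumble bias TB ~0.04 vs ~0.12 for liquid-grown cells), swim faster
(~25 vs ~21 µm/s), and their flagellar motors reverse less often (~9 vs ~38
reversals/min) while spinning faster (~78 vs ~68 Hz). The cause is a
post-transcriptional ~1.5× elevation of the CheZ phosphatase, driven by
protein stabilization (degradation ~2.7×10⁻³ min⁻¹ in liquid vs ~1.5×10⁻⁴
min⁻¹ in swarmers), which lowers steady-state CheY~P and with it the motors'
clockwise bias.

`swarmotility` is an R package for scientists who study bacterial motility
and chemotaxis signaling. It implements, end to end and with seeded
synthetic-data generators for every input type:

* **Synthetic data** — pseudo-2D run-and-tumble swimming populations with
  Brownian non-motile cells, rendered phase-contrast-like movies,
  tethered-bead CW/CCW motor telegraph traces at 1250 frames/s,
  chloramphenicol-chase protein decay courses, Western-blot band
  intensities, and two-channel fluorescence scenes — each parameterized by
  condition presets (`LIQUID`, `SWARM`, `HARD`) carrying the published
  values as ground truth.
* **Tracking** — temporal-mean background subtraction, matched filtering,
  radial-symmetry subpixel localization with Monte-Carlo-calibrated
  FDR-controlled thresholding, exact bipartite motion-model linking, and a
  minimum-duration filter.
* **Motility statistics** — MSD-based motile classification (10 µm²/s
  threshold), run/tumble segmentation, tumble bias (fraction of tumbling
  frames), tumble-excluded swimming speed, and duration-weighted population
  summaries.
* **Motor analysis** — signed rotation frequency (CW positive), debounced
  reversal counting, and torque τ = 2πf·ξ with the bead drag model
  ξ = 8πηa³ + 6πηa·r_e².
* **Blot / fluorescence quantification** — loading-normalized fold changes,
  log-linear degradation-rate fits, per-cell two-channel totals and
  CheZ/CheY expression ratios.
* **Statistics** — trajectory-weighted one-way ANOVA
  F = [Σ_g W_g(ȳ_g−ȳ)²/(K−1)] / [Σ_i w_i(y_i−ȳ_{g(i)})²/(n−K)]
  with a permutation null (labels permuted at the trajectory level) and a
  Kolmogorov–Smirnov comparison with the analytic F(K−1, n−K).
* **Signaling model** — the Goldbeter–Koshland futile-cycle steady state for
  CheY~P with a Hill motor response, quantifying why zero-order
  ultrasensitivity lets a ~1.5× CheZ change collapse the tumble bias.

## Worked example

Simulate both conditions, recover their motility statistics, and test the
difference:

```r
library(swarmotility)

recover <- function(cond) {
  pop  <- simulate_population(make_preset(cond), n_cells = 150,
                              duration = 60, dt = 0.1, seed = 1)
  samp <- filter_short(pop$samples, 5)
  sm   <- summarize_motility(samp)
  sm$condition <- cond
  sm
}
liq <- recover("LIQUID"); swa <- recover("SWARM")
unlist(population_summary(liq)[c("tb_median", "speed_median")])
#>    tb_median speed_median 
#>    0.1183333   20.8987305 
unlist(population_summary(swa)[c("tb_median", "speed_median")])
#>    tb_median speed_median 
#>   0.03666667  24.96697371 

both <- rbind(liq, swa); both <- both[both$is_motile, ]
permutation_pvalue(both$tumble_bias, both$condition, both$weight,
                   n_perm = 1000, seed = 1)
#> Weighted one-way ANOVA, permutation null
#> F = 1476 on (1, 272) df; n = 274, K = 2; p = 0.000999 (1000 perms)
```

The recovered medians sit on the condition presets (TB 0.12 vs 0.04, speeds
21 vs 25 µm/s), and the weighted permutation ANOVA rejects equality of the
tumble-bias distributions at the smallest p-value 1000 permutations can
resolve (the add-one estimator never returns 0).

The futile-cycle model shows why a modest CheZ elevation does this:

```r
chez_fold_sweep(c(1, 1.3, 1.5))[, c("fold", "tumble_bias")]
#>   fold  tumble_bias
#> 1  1.0 1.200000e-01
#> 2  1.3 3.731582e-11
#> 3  1.5 3.418159e-13
```

In the zero-order (enzyme-saturated) regime, a 1.3× phosphatase increase
drives the predicted tumble bias from the calibrated 0.12 to nearly zero;
with unsaturated enzymes (`futile_cycle_params(K_A = 10, K_Z = 10)`) the
same fold barely moves it.

## Package layout

| Path | Contents |
| --- | --- |
| `R/presets.R`, `R/simulate.R`, `R/render.R` | condition presets and all generators |
| `R/tracking.R` | detection, linking, duration filter |
| `R/motility.R` | diffusion, segmentation, bias/speed, population summaries |
| `R/motor.R` | bead-trace analysis and torque |
| `R/blotquant.R`, `R/fluorquant.R` | blot and fluorescence quantification |
| `R/stats.R` | weighted permutation ANOVA |
| `R/signaling.R` | futile-cycle / ultrasensitivity model |
| `R/io.R`, `inst/scripts/swarm-pipeline.R` | CSV/TIFF/JSON I/O, pipeline driver, CLI wrapper |
| `vignettes/swarmer-motility-methods.Rmd` | models, calibration choices, limitations |
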