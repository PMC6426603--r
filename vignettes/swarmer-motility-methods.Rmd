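---
title: "Models and methods behind swarmotility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swarmotility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmotility)
```

# The scientific question

Swarming *Escherichia coli* populations remodel their chemotaxis physiology:
cells lifted from a swarm edge into liquid tumble far less (median tumble
bias ~0.04 versus ~0.12 for liquid-grown cells) and swim faster (~25 versus
~21 um/s). The proximate cause is a post-transcriptional elevation of the
CheZ phosphatase (about 1.5-fold, driven by protein stabilization: CheZ
degrades at ~2.7e-3 per min in liquid-grown cells versus ~1.5e-4 per min in
swarmers), which lowers steady-state CheY~P and hence the motors' clockwise
bias. Single tethered-motor recordings corroborate the behavior: ~38
reversals per minute at ~68 Hz for liquid-grown motors versus ~9 reversals
per minute at ~78 Hz for swarmer motors.

These are measurements on live cells; no raw data are deposited, so the
package reproduces them as *calibrated parameter-recovery experiments*:
seeded generators emulate each raw data type with the published condition
values as ground truth, and the analysis pipeline must recover those values
from the generated data. Everything below describes either a generator (what
structure it produces and why) or an estimator (how a quantity is measured
and which choices were open).

# Run-and-tumble trajectory model

A motile cell alternates runs and tumbles. We simulate the state sequence as
a **discrete-time two-state Markov chain at the frame interval** `dt`
(default 0.1 s, matching 10 frames/s video): the per-frame exit
probabilities are `dt / mean_run_duration` and `dt / mean_tumble_duration`,
giving geometric dwell times — the discrete analogue of exponential run and
tumble durations. We chose the discrete chain over a continuous-time
simulation because its stationary tumbling fraction equals
`tumble_bias_true` *exactly* (the continuous process sampled at frames
introduces partial-frame boundary effects of order `dt/mean_tumble`, i.e.
tens of percent at these frame rates), which makes the generator a clean
ground truth for calibrating the tumble detector.

Parameters, units and defaults:

* `run_speed` (um/s): asymptotic run speed; 21 (liquid/hard) or 25 (swarm).
* `tumble_bias_true`: 0.12 (liquid/hard) or 0.04 (swarm). Hard agar is
  behaviorally liquid-like because hard agar does not support swarming and
  abolishes the response.
* `mean_tumble_duration` (s): 0.2. The source study reports only the bias,
  not the dwell-time law; 0.2 s is the literature-typical tumble duration,
  and the mean run duration follows from the identity
  `mean_run = mean_tumble * (1 - TB) / TB`.
* `speed_recovery_tau` (s): 0.17. Cells need roughly half a second to regain
  full swimming speed after a tumble; an exponential relaxation with
  tau = 0.17 s reaches ~95% recovery at 0.5 s. Displacement over each frame
  is the exact integral of the recovery curve, not a midpoint approximation.
* `rotational_diffusion` (rad^2/s): 0.06 during runs. Tumble reorientation
  is drawn uniformly on [0, 2pi) — the turn-angle law is not reported, and a
  uniform draw makes the detector calibration conservative (no residual
  direction correlation to exploit).
* `localization_sigma` (um): 0.05. Radial-symmetry centroiding is good to
  ~0.05–0.1 px at moderate signal-to-noise; at 0.65 um/px that is
  0.03–0.065 um, and we take the middle of that range.
* `nonmotile_fraction`: 0.1, with non-motile cells performing pure Brownian
  motion at `brownian_D` = 0.4 um^2/s (the Stokes–Einstein scale for a ~1 um
  particle), far below the 10 um^2/s motile-classification threshold.

What the generator deliberately does **not** emulate: cell–cell collisions
and hydrodynamic interactions, out-of-plane excursions in the pseudo-2D
chamber, gradual behavioral drift after transfer from the swarm, and
cell-to-cell variability in `run_speed` or `tumble_bias_true` (all cells of
a condition share one parameter set). Passing the recovery tests therefore
shows that the estimators are calibrated for the assumed motion model, not
that they are robust to every artifact of real video.

# Tumble segmentation and its calibration

The segmenter labels each frame interval RUN or TUMBLE from the
instantaneous speed relative to a rolling median reference (window 2 s,
floored at the trajectory's 70th speed percentile so that bursts of tumbles
cannot drag the reference down). The detector was calibrated against the
generator's ground-truth state labels, which led to three choices that
differ from the obvious defaults:

* **Threshold `alpha` = 0.15**, not ~0.5. During the post-tumble speed
  recovery the first frame moves at only ~25% of the run speed; a 0.5
  threshold systematically mislabels that frame as tumbling and inflates the
  bias by tens of percent. 0.15 sits between the tumble noise floor
  (~1 um/s at the default localization noise) and the first recovery frame
  (~5 um/s), and recovers the bias to within ±0.003 across
  `tumble_bias_true` from 0.02 to 0.2.
* **Turn-rate channel off by default** (`omega_min = Inf`). A turn-rate test
  cannot separate a tumble frame from the first recovery frame, because the
  direction reference entering that frame is the noise-dominated tumble
  displacement; with the uniform reorientation law it fires on ~87% of
  recovery frames. The channel remains available for data whose tumbles
  translate appreciably.
* **No hysteresis merging** (`merge_gap = 0`). Merging run gaps < 0.2 s
  between tumbles relabels genuine one-frame runs, biasing the bias upward
  by up to +0.013 at high tumble bias. The generator produces no detection
  dropouts that merging would repair; the parameter is exposed for noisy
  real data.

**Swimming speed** is the mean frame displacement over run frames,
*excluding a 0.5-s post-tumble recovery window*. A plain run-frame mean
under-reports the liquid-condition speed by ~12% (tau = 0.17 s against a
mean run of 1.47 s); excluding the recovery window — set to the ~0.5 s the
cells are known to need — recovers the asymptotic speed to within ~1%. Population summaries weight each cell
by its trajectory duration; the weighted median is defined so that integer
weights reproduce the plain median of the frame-expanded sample exactly.

**Motile classification** fits `MSD(tau) = 4 D tau` through the origin over
lags 2–10 s and calls a cell motile when `D >= 10` um^2/s (boundary
inclusive — the boundary side is not specified in the source and must be
fixed somewhere).

# Tracking

Rendered movies draw each cell as a Gaussian spot (sigma 1.2 px) on a flat
background with Gaussian pixel noise; `snr` is the peak amplitude over the
noise SD. The tracking pipeline is background subtraction (temporal mean,
clipped at zero), matched filtering with the spot kernel, local-maxima
candidates 2 robust SDs above the frame median, an FDR-controlled keep/drop
decision, radial-symmetry subpixel refinement, and global nearest-pattern
linking:

* **Detection null.** The null distribution of noise maxima after
  clipping and filtering is awkward analytically (clipping skews it,
  filtering correlates it), so it is calibrated per stack by Monte Carlo:
  synthetic Gaussian fields with the residual's robust background scale are
  pushed through the identical clip/filter/maxima pipeline and a Gumbel law
  is fitted to their maxima; candidate p-values are its upper tail, and
  Benjamini–Hochberg at `fdr = 0.05` is applied per frame. On pure-noise
  stacks the realized per-frame false-discovery proportion stays within
  1.5x nominal; on 200-cell scenes at snr 5 recall and precision both
  exceed 95%.
* **Robust scale from quantiles.** Background statistics use the median and
  the 97.5% quantile, which are unchanged by zero-clipping (an SD computed
  from clipped residuals would be badly underestimated).
* **Linking** solves an exact bipartite minimum-cost assignment per frame
  (Jonker–Volgenant; verified against brute-force enumeration). The pairing
  cost is the cheaper of the constant-velocity prediction distance and the
  current-position distance (the two motion hypotheses), gated at the
  maximum expected displacement (speed range 20–30 um/s) plus slack; tracks
  may coast one frame (gap closing, the gap interpolated linearly).
  Multi-hypothesis track graphs are out of scope.
* Trajectories shorter than 5 s are discarded before analysis.

# Tethered-bead motor analysis

The generator runs a continuous-time two-state telegraph process with exit
rates `k(CCW->CW) = R/(2(1-b))` and `k(CW->CCW) = R/(2b)` for reversal rate
`R` (sign changes per minute) and CW time-fraction `b`, so both the reversal
rate and the CW bias are matched in expectation; the bead orbits at
`orbit_radius` 0.2 um with Gaussian center jitter (0.01 um) at 1250
frames/s. Defaults: 68 Hz / 38 rev/min / b = 0.12 (liquid); 78 Hz /
9 rev/min / b = 0.03 (swarm); the CW and CCW speeds are equal because the
source reports a single unsigned speed per motor.

The analyzer recovers the orbit center as the coordinate-wise median,
unwraps the bead angle, and differentiates it with a Savitzky–Golay local
quadratic over 8 ms (the smoothing window is our choice; it spans ~10
samples, well below the shortest typical dwell of ~0.4 s). Sign convention:
CW positive, CCW negative; speed summaries report magnitudes. Reversals are
zero crossings whose new sign persists at least 10 ms (debounce), normalized
per minute. At the default rates the debounce loses the ~3% of dwells
shorter than 10 ms, a bias well inside the acceptance tolerances.

**Torque** uses the rotational-plus-eccentric drag
`xi = 8 pi eta a^3 + 6 pi eta a r_e^2` with eta = 9.6e-4 Pa s (aqueous
buffer at ~22 C), a = 0.375 um (0.75-um bead) and eccentricity r_e = 0.2 um,
and `tau = 2 pi f xi`. The eccentricity of the original calibration is not
printed anywhere we can verify, so **absolute** torques are
calibration-sensitive (the defaults give ~659 pN nm at 68 Hz, close to the
published 644 ± 21); only the condition **ratio**, which cancels `xi`, is
treated as reproducible, and every torque output is interpreted together
with its drag model.

# Blot and fluorescence quantification

Band intensities are normalized by the same-lane loading control before any
log transform; condition fold changes are ratios of mean normalized levels
with a two-sided two-sample t-test on the per-replicate values. Decay
courses are fitted per replicate by OLS on log intensity (the
maximum-likelihood estimator under multiplicative lognormal noise), then
aggregated as mean ± SD; the fit window is configurable and defaults to all
points. Chase sampling covers 0–360 min every 15 min — the window over
which the protein's stability was followed — because resolving the slow
swarm-condition rate (1.5e-4 per min, a 5% total decay against 10% per-band
noise) needs both the full window and dense sampling; even so, the
six-replicate mean of that rate has a sampling SD of roughly half its value,
which is the honest precision limit of this design (the liquid-condition
rate is recovered to a few percent).

Fluorescence scenes place non-overlapping elliptical cells (1:3 aspect) with
lognormal per-cell totals in both channels, cellular autofluorescence,
uniform background, and Poisson shot noise. Quantification segments the
summed image (Otsu threshold, hole filling, distance-map watershed to split
touching pairs), discards cells more than 3 SD from the mean area (<5% of a
Gaussian-area population), sums background-subtracted pixels per cell, and
subtracts a per-cell autofluorescence constant; negative corrected totals
are clipped to zero with a warning rather than dropped. Illumination is
modeled as flat because the synthetic scenes are flat; the functions accept
externally estimated backgrounds for real data. The CheZ/CheY readout is
reported both as the ratio of condition medians of per-cell
cherry/yfp ratios and as the ratio of mean ratios, since the two differ
under skewed expression distributions.

# Trajectory-weighted permutation ANOVA

With per-cell weights (trajectory durations) normalized so they sum to the
number of cells,

$$F = \frac{\sum_g W_g(\bar y_g - \bar y)^2 / (K-1)}
          {\sum_i w_i (y_i - \bar y_{g(i)})^2 / (n-K)},$$

which reduces exactly to the classical one-way F under unit weights. The
null is generated by permuting condition labels at the *trajectory* level
(value and weight travel together), and the p-value uses the add-one
estimator `p = (1 + #{F* >= F}) / (1 + n_perm)`, which cannot return zero
and remains valid for non-normal data — the reason a permutation null is
used at all. With near-normal values and unit weights the permutation null
matches the analytic F(K-1, n-K) density (Kolmogorov–Smirnov distance
< 0.05 at n = 1000, K = 3, 10,000 permutations), validating the analytic
reference where its assumptions hold.

# Futile-cycle model of the CheZ effect

Why does a ~1.5-fold CheZ change collapse the tumble bias ~3-fold? CheA
(kinase) and CheZ (phosphatase) act on a shared CheY pool in a futile cycle.
At steady state the phosphorylated fraction solves
`V_A (1-Y)/(K_A + 1-Y) = V_Z Y/(K_Z + Y)`; the closed form is the root in
[0,1] of the corresponding quadratic, evaluated with the numerically stable
quadratic formula and verified against bisection to 1e-9. When both enzymes
are saturated (`K_A, K_Z << 1` — the regime for chemotaxis, where CheY far
outnumbers both enzymes), the steady state is **ultrasensitive** to
`V_A/V_Z`: the log-log sensitivity at the balance point grows without bound
as the Michaelis constants shrink (zero-order ultrasensitivity).

Tumble bias follows from CheY~P through a Hill motor response with
K_half = 3.1 uM, Hill coefficient 10, and total CheY 9.7 uM — standard
chemotaxis literature values, configurable and logged; the source study
commits to no quantitative pathway parameters, so this module is an
illustrative companion model, not a fitted result. `chez_fold_sweep()`
calibrates `V_A/V_Z` so the baseline bias is 0.12 and then scales the
phosphatase: in the zero-order regime a 1.3–1.5x CheZ elevation drives the
predicted bias below 0.06 (at these steep motor parameters, essentially to
zero), while in a first-order regime (`K = 10`) the same fold barely moves
the phosphorylated fraction. Adaptation kinetics (CheR/CheB methylation) are
held at steady state; the argument concerns the kinase/phosphatase ratio,
not adaptation.

# Problem sizes, tolerances and degenerate inputs

The recovery experiments use the source conditions directly: 500 cells x
100 s at 10 fps per condition for the trajectory statistics (tolerances
±0.015 on the bias medians, ±1.5 um/s on the speeds), 200 bead traces x
60 s at 1250 fps per condition for the motor statistics (±3 and ±2
reversals/min, ±2 Hz), six chase replicates and six blot replicates for the
biochemistry. Unit and property tests run the same machinery at reduced
sizes (tens of cells, seconds of video, hundreds of permutations) chosen so
that each assertion still has a comfortable margin over its Monte-Carlo
noise. Degenerate inputs are contracts, not accidents: flat frames detect
nothing, all-identical ANOVA input raises a distinguishable error, a
zero-radius orbit refuses frequency estimation, non-positive intensities
refuse a log fit, and a zero-tumble preset yields a straight track with
bias exactly 0.

# Known limitations

* All trajectory estimators assume the generator's motion model; real
  swarm-derived cells show cell-to-cell parameter variability and
  near-surface hydrodynamic effects that are not emulated.
* The tumble detector's constants are calibrated to the default
  localization noise and frame rate; other imaging conditions need
  recalibration (the constants are exposed as arguments).
* Absolute motor torque depends on an unverifiable drag eccentricity; only
  torque ratios are calibration-free.
* The swarm-condition degradation rate is at the edge of what six noisy
  replicates can measure, as quantified above.
* The signaling module ranks mechanisms (zero-order vs first-order), but
  its absolute bias predictions inherit the assumed Hill parameters.
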