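---
title: "Breathing-modulated block designs for olfactory fMRI: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing-modulated block designs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sniffglm)
```

## The model

Olfactory stimulation is gated by breathing: odorants reach the receptor
sheet only while the participant inhales. When odorants are delivered in
sustained blocks (here 16 s of odorant alternating with 16 s of odorless
air, after a 16 s odorless lead-in, 208 s per run), the underlying neural
drive is therefore better described as a train of brief inhalation-locked
bursts than as a block-long plateau. `sniffglm` implements both descriptions
as GLM design matrices on the acquisition grid (104 volumes, TR 2 s, in the
defaults) and provides the machinery to compare them:

* **SBD1/SBD2** (standard block designs): unit boxcars over the odorant
  (and, for SBD2, air) phases, convolved with a dual-gamma hemodynamic
  kernel.
* **MBD1/MBD2** (inhalation-modulated block designs): unit mini-boxcars over
  the 2 s windows preceding each detected inhalation peak, restricted to
  events that fall entirely within one phase, convolved with the same
  kernel.

All design matrices carry a constant column; contrasts are keyed by
predictor name (SBD1/MBD1 contrast the single task predictor, SBD2/MBD2 the
difference odorant − air).

### Respiratory preprocessing

The belt signal (400 Hz in the defaults) passes through four stages:

1. **Rolling median**, window 100 ms (40 samples at 400 Hz). The window is
   centered; an even window takes one extra sample on the left, and the
   median of an even count is the mean of the two central order statistics.
   At the edges the window shrinks to the available samples.
2. **Downsampling to 1 Hz** by averaging non-overlapping windows — a crude
   anti-aliasing choice; the integer ratio requirement is enforced.
3. **z-transform** with the population (1/n) variance. A constant trace is a
   degenerate input and raises an error rather than producing NaNs.
4. **Iterated root normalization**: `y <- y / |y|^(1/p)` applied
   `n_iterations` times (defaults `p = 2`, 4 iterations), equivalently
   `sign(y) |y|^((1-1/p)^k)`, i.e. `sign(y) |y|^(1/16)` at the defaults.
   Zero maps to zero by continuity; ±1 are fixed points; the ordering of
   absolute values is preserved. The transform compresses the trace towards
   (−1, 1) so that step changes in belt gain — the physiological monitoring
   unit recalibrates itself at unpredictable times — leave the peak
   structure intact.

Peaks are then local maxima with **topographic prominence** of at least 0.75
(normalized units) and at least 2 s apart. Prominence is computed by walking
out from each maximum to the first strictly higher sample or the trace
boundary and taking the higher of the two side minima as the base. The
separation rule is enforced greedily in descending order of prominence, ties
going to the earlier peak; "at least 2 s" is inclusive. Peak times stay on
the 1 Hz sample grid — no sub-sample interpolation. A run of equal samples
higher than both neighbours is a single maximum located at the upper-middle
sample of the run; this matters only for perfectly symmetric signals (such
as the noiseless simulator below, where a mid-cycle peak straddles two 1 s
averaging windows) and the upper-middle choice keeps the first breath of a
run usable (its 2 s pre-peak window still starts at or after t = 0).

Each retained peak yields one **inhalation event** covering the 2 s that
precede it. Events whose window would begin before the run are dropped, not
clipped. Phases are half-open intervals `[start, end)`; an event belongs to
a phase iff `onset >= start` and `onset + duration <= end`, and events
straddling a boundary stay `unassigned` and enter no regressor.

### The hemodynamic kernel and its calibration

The kernel is the canonical difference of two gamma densities (shape =
delay/dispersion, scale = dispersion), sampled on 32 s of support; with unit
dispersions the positive lobe peaks at `peak_delay − 1` seconds and the
kernel is exactly zero at t = 0. Regressors are built on a 1 Hz grid (the
respiratory resolution), convolved by direct filtering (so structural zeros
stay exact), and sampled at the volume onsets `t = 0, TR, 2·TR, ...`; no
slice-timing offset is applied. Boxcars are half-open: the sample at a
block's end time is off.

Absolute design-efficiency values depend on the kernel's amplitude
convention, which standard treatments leave open (any rescaling of the
kernel by `a` multiplies every efficiency by `a²` and cancels from ratios
and orderings). Three conventions are available: `sum1` (unit-sum sampled
kernel, so block plateaus sit at the boxcar height), `peak1` (unit
maximum), and the default `calibrated`. The calibrated convention fixes the
two parameters that the literature leaves loosest — the undershoot ratio and
the overall amplitude — by requiring that the default schedule reproduce the
reference block-design efficiencies this implementation is validated
against, `SBD1 = 58.036` and `SBD2 = 33.614`. Solving those two equations
once gives `undershoot_ratio = 0.21528830` (between the common 1/6 and 0.35
choices) and amplitude `1.03711398 ×` the unit-sum kernel. These constants
are frozen in the package; they were computed once from the deterministic
schedule and are not adjusted anywhere else.

### Design efficiency

Efficiency of a contrast `c` on design `X` is `1 / (c (XᵀX)⁻¹ cᵀ)`. Two
choices deserve note:

* **The constant column is excluded from the efficiency computation**
  (treated as a nuisance term), while always remaining in the design used
  for model fitting. With the constant inside `X`, the air and odorant
  boxcars of SBD2 sum to a near-constant, which pins the differential
  contrast's efficiency to essentially the SBD1 value; the reference values
  for SBD1 and SBD2 (ratio ≈ 1.727) are only consistent with the
  task-predictors-only computation, so that is the convention implemented.
* **A reciprocal-condition-number guard** (`rcond < 1e-12` on `XᵀX`) raises
  an explicit rank error instead of returning an unstable inverse;
  duplicated predictors or an all-zero event regressor fail loudly.

Study-level summaries follow the averaging scheme: efficiency per run, mean
across runs within subject, then mean and sd across subjects. The standard
block designs depend only on the schedule and are computed once.

### Multi-level statistics

Run-level fits are ordinary least squares per voxel (QR, residual variance
RSS/dof). The aggregation across runs is not uniquely determined by common
practice; this package uses the simplest defensible choice, a
**fixed-effects mean of run-level contrast estimates** per subject, followed
by a **random-effects one-sample t** across subjects (dof n − 1). z maps are
obtained from t maps by the sign-preserving two-sided transform
`z = sign(t) Φ⁻¹(1 − p/2)` with `p` the two-sided t-tail probability,
evaluated in log space so extreme t values do not overflow. FDR control is
Benjamini–Hochberg on two-sided p-values; the realized |z| threshold is
reported alongside the mask. Effect sizes are one-sample Hedge's g against
zero with the small-sample correction `J = 1 − 3/(4(n−1) − 1)`. The winner
map takes the per-voxel argmax over the four g maps wherever the maximum
exceeds the threshold (default 0.4), with ties broken by the fixed order
SBD1 < SBD2 < MBD1 < MBD2; masked values never win. Voxels with zero
residual or between-subject variance are masked (NA) rather than zeroed —
except the all-zero voxel, which maps to a statistic of 0 by convention —
and masks propagate through levels.

Habituation profiles refit each run with one predictor per odorant block
(the block's boxcar for SBD strategies, the block's inhalation events for
MBD strategies, plus the strategy's air predictor for the `*2` variants);
an odorant block with no events under an MBD strategy is masked rather than
estimated.

## The synthetic-data generator

`simulate_breathing()` emulates resting nasal breathing as recorded by a
scanner belt: cycles whose lengths are lognormal with mean `60/rate` and
coefficient of variation `cycle_jitter_cv`; each cycle is a raised-cosine
bump around a zero baseline (−0.5 at cycle edges, +0.5 at the mid-cycle
inhalation peak — belt signals are AC-coupled, and a zero-mean waveform is
what makes gain jumps survivable by the z-transform); a piecewise-constant
gain with Poisson-timed jumps to a log-uniform value in `[0.2, 5]`,
emulating hardware recalibration; and additive Gaussian noise proportional
to the current gain. Defaults: rate 14.5/min with between-subject sd
3.1/min (truncated above 5/min), within-subject cycle CV 0.15, 0.3 jumps
per minute, noise 5% of breath amplitude, 400 Hz. The rate statistics
mirror what resting participants show in the scanner; the cycle CV,
the jump process and the waveform shape are modelling choices exposed as
parameters, constrained only qualitatively.

`simulate_bold()` builds a ground-truth neural signal — either 2 s bursts at
the labelled inhalation events (odorant bursts attenuated block-by-block by
a habituation profile, default monotone `1, .8, .6, .5, .4, .3`) or a
sustained per-block plateau — convolves it with the same kernel, samples at
the TR, and adds AR(1) Gaussian noise (default lag-1 coefficient 0.3,
burn-in discarded) to active and null voxels. `generate_study()` derives
every run's seed from one master seed, so a study regenerates byte-identical
from its manifest.

What the generator deliberately does **not** emulate: odorant-specific
response differences, spatial correlation between voxels, scanner drift and
motion, respiratory waveform asymmetries (inhalation/exhalation timing), or
amplitude variation across breaths. Passing tests on this generator
demonstrate the internal consistency of the pipeline — event recovery,
unbiased amplitude estimation, the efficiency ordering, and the
regime-dependence of detection power — not performance on any particular
real cohort.

## Numerical choices and degenerate inputs

* Even-window rolling median: centered with the extra sample on the left;
  edge windows shrink.
* Downsampling requires an integer rate ratio; constant traces raise an
  error at the z-transform.
* `y = 0` maps to 0 in the normalization (continuous limit).
* Plateau maxima resolve to the upper-middle sample; separation ties to the
  earlier peak.
* Events are dropped (not clipped) when their window precedes the run.
* Boxcars and phases are half-open `[start, end)`.
* `rcond < 1e-12` on the efficiency Gram matrix is treated as rank
  deficiency.
* An MBD design with no `i_odorant` events is a degenerate-design error;
  within a study runner (`run_comparison`, or `efficiency_study` with
  `on_error = "skip"`) such runs are isolated and recorded, not fatal.
* Zero-variance voxels are masked; the all-zero voxel yields statistic 0.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run entirely on synthetic
data: the efficiency study uses 33 subjects × 12 runs of 208 s breathing
(traces only, no BOLD); parameter-recovery checks use single runs with a
handful of voxels plus a 200-replicate noise study; the detection-power
comparison uses 8 subjects × 4 runs with 12 active and 12 null voxels per
run, under both inhalation-locked and sustained ground truth with
irregular breathing (cycle CV 0.25). These sizes were chosen so each
property is measured with comfortable statistical power while the whole
suite stays desk-scale.

## Known limitations

* The amplitude calibration makes absolute efficiencies meaningful only
  relative to the shipped convention; cross-study comparisons should use
  ratios or orderings, which are convention-free.
* The fixed-effects subject level ignores run-level variance differences; a
  precision-weighted variant would need the per-run standard errors.
* Event regressors inherit the 1 Hz respiratory grid; onsets are not
  interpolated below 1 s.
* Spatial smoothing is provided only as an explicit utility for maps with
  geometry; nothing is smoothed implicitly.
* The habituation refit estimates one amplitude per block; it does not
  model within-block adaptation.
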