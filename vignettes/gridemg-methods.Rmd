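---
title: "Spatial analysis of high-density surface EMG: models and methods"
author: "gridEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial analysis of high-density surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridEMG)
```

## The measurement and its representation

High-density surface EMG (HDsEMG) samples the myoelectric activity of one
muscle with a two-dimensional grid of closely spaced electrodes — here by
default a 13 x 5 grid with one absent corner electrode (64 channels), 8 mm
inter-electrode distance, sampled at 1024 Hz, the configuration typical of
commercial semi-disposable arrays used on knee-extensor muscles. The row
axis of the grid runs along the muscle-fiber direction.

The package's central object is the **activation map**: for a time window,
the RMS amplitude of each channel placed at its grid position,

$$HM_{ij} = \mathrm{RMS}(sEMG_{ij}),$$

a spatial image of how strongly each region under the grid is active.
Everything downstream — scalar features, barycentre estimates, their time
courses — is a functional of these maps.

### Preprocessing

Signals are band-pass filtered to 20–400 Hz before mapping: movement
artefact and baseline drift live below 20 Hz, and surface-recorded
myoelectric power is negligible above 400 Hz. The filter is a 4th-order
Butterworth applied forward–backward (zero phase). The family and order are
a package choice — standard surface-EMG practice — made because zero-phase
filtering preserves envelope timing, which matters for barycentre
trajectories; the band edges are the conventional analysis band.

**Single-differential derivation** subtracts each channel from its
neighbour one row further along the fiber axis,
$sd_{ij} = s_{ij} - s_{i+1,j}$. Components common to all electrodes
(far-field crosstalk, line interference residue) cancel exactly. Pairs
touching the missing corner are dropped, so the default 64-electrode grid
yields **59** differential channels on a 12 x 5 grid. Which corner of the
array is absent is hardware-specific; the package defaults to position
(1, 1) and makes it configurable, since analyses depend only on the count
and mask, not on which corner is absent.

**Contraction segmentation** thresholds a smoothed effort signal — the
dynamometer torque when present (the natural choice for isokinetic trials),
else the grid-mean rectified EMG envelope — at 10% of its peak, taking the
first and last crossing. Smoothing is a 100 ms moving average; the torque
channel is kept at its native 100 Hz and crossings are converted to EMG
samples by nearest-sample mapping.

### Analysis windows

Two window conventions coexist in this field: coarse 1 s intervals for long
holds, and a short epoch (250 ms) centred at the contraction midpoint for
feature extraction. The package treats window length as a parameter with a
0.25 s default, because trajectory analysis of a 2–5 s isokinetic effort
needs several maps per contraction; `windowS = 1` reproduces the coarse
convention. Windows tile the segment without overlap by default
(`overlapFrac` exposes overlap for sensitivity analyses).

## Scalar map features

From the midpoint-epoch maps, `featureSet()` computes six scalars:

* **Intensity** $I = \log_{10}\left(\frac{1}{N}\sum_{ij} HM_{ij}\right)$,
  in log10-mV, compressing the non-linear amplitude–force relation.
  By construction $I = \log_{10}(\text{mean RMS})$ exactly.
* **Differential intensity** $DI$: the same log-of-mean applied to the
  59-channel single-differential map. The per-pair definition
  $\log_{10}(\mathrm{RMS}(s_{ij}-s_{i+1,j}))$ yields one value per pair;
  reporting one value per trial requires an aggregation convention, and the
  package aggregates as the log of the mean differential RMS so that $DI$
  mirrors $I$'s structure and both shift by exactly +1 per tenfold
  amplitude scaling.
* **Modified entropy**
  $E = -\sum_i q_i \log_2 q_i$, $q_i = HM_i^2 / \sum_k HM_k^2$, in bits
  over the valid channels: maximal ($\log_2 N$, 5.8826 bits for 59
  channels) for a spatially uniform map, 0 when one channel carries
  everything. Low entropy means a heterogeneous, localised activation
  pattern.
* **CoV** $= 100\,\mathrm{SD}/\mathrm{mean}$ of the channel RMS values, in
  percent — the complementary heterogeneity index (uniform map: 0).
* **Mean RMS**, in mV.
* **Median frequency**: per channel, the frequency dividing the epoch's
  power spectrum into equal halves, averaged over channels.

### Which map feeds which feature

A design question with no single established answer is whether the
heterogeneity and amplitude features are computed on monopolar or
single-differential maps. The package's canonical routing is:

* entropy and CoV on the **differential** map — its channel count (59 on
  the default grid) is the field's usual normalisation, and differencing
  removes the common-mode floor that would otherwise flatten the
  topography and inflate entropy;
* intensity and mean RMS on the **monopolar** map, preserving the identity
  $I = \log_{10}(\text{mean RMS})$;
* differential intensity on the differential map.

Computing *all* amplitude features on the differential map would make $I$
and $DI$ the same number under any log-of-mean convention; keeping
intensity monopolar keeps the two features distinct measurements, which is
how they behave in published feature tables. Median frequency is computed
on the monopolar epoch (the choice moves the estimate only through the
differencing filter's gentle high-pass tilt, and either convention stays
inside the analysis band).

### Numerical conventions

* RMS maps and all amplitude features are in mV; unit conversion happens
  once at load (`V`, `mV`, `uV` sidecar declarations).
* Median frequency uses a Hann-windowed periodogram with the mean removed;
  on the discrete spectrum the median is the smallest frequency bin whose
  cumulative power reaches half the total, with ties (to within a 1e-6
  relative leakage allowance) resolved toward the lower frequency. For two
  equal-power tones the convention therefore lands at the upper edge of
  the lower tone's spectral lobe.
* Silent channels (RMS below 1e-12 mV) are excluded from the median-
  frequency average; bad channels flagged in the sidecar are masked out of
  every map and count.
* All-zero maps are errors for entropy, CoV, intensity and CoG, not NaNs:
  a silent grid is a data problem the caller should see.

## Centre-of-gravity estimation

The barycentre of a map,

$$\mathrm{CoG} = \frac{\sum_{ij} HM_{ij}\,(i, j)}{\sum_{ij} HM_{ij}},$$

localises the activity in electrode-index units, weighting linearly in the
amplitudes. The **x coordinate is the row (fiber-axis) coordinate** and y
the column coordinate. On a uniform full 13 x 5 grid the centroid is
(7, 3). Published coordinate magnitudes on this grid (x about 6–7, y about
3) are only consistent with this axis assignment, so the package uses it
even though anatomical labels for the axes vary between reports.
Coordinates can be converted to mm by multiplying with the
inter-electrode distance; tables stay in index units because that is how
grid positions are defined.

Two estimators are provided:

* **Point-based** (`cogReference()`): reduce the contraction to one
  reference map — midpoint window, peak-intensity window, or the window at
  the torque peak — and take its CoG. Peak intensity is the default for
  dynamic efforts.
* **Trajectory-based** (`cogTrajectory()`): the CoG of every window from
  contraction start to end, summarised per axis by mean, variance, SD and
  min–max range. The trajectory retains within-contraction spatial drift
  that the point estimate discards.

`compareCoGMethods()` quantifies their agreement with a per-axis Pearson
correlation across trials (grouped by speed when group sizes allow),
reporting r, r² and the two-sided p.

Two estimator properties worth knowing when interpreting trajectories on
real or synthetic data:

* **Boundary truncation.** A source centred near a grid edge has part of
  its spatial weight outside the electrode array; the measurable centroid
  is pulled toward the grid interior. For a Gaussian envelope this bias
  grows with the spread: a spread of 3 rows centred at row 4 of 13 biases
  the centroid by roughly half a row, while a spread of 1.5 rows keeps it
  under 0.1. Range-recovery checks therefore use compact sources.
* **Noise-floor pull.** Additive noise contributes RMS to every channel
  uniformly, dragging the CoG toward the grid centroid at low
  signal-to-noise; this matters only in the lowest-effort windows near
  segment edges.

## Group statistics

The statistical layer mirrors standard practice for within-subject speed
comparisons: Shapiro–Wilk normality screening per feature and condition,
two-sided paired t-tests between every pair of speed conditions with
Bonferroni adjustment ($p_\text{adj} = \min(1, p \cdot n_\text{pairs})$,
family-wise alpha 0.05), and Pearson correlation for method agreement.
These wrap the standard R implementations (`shapiro.test`, `t.test`,
`p.adjust`, `cor.test`); identical paired samples are reported as t = 0,
p = 1 by convention rather than erroring. The number of Bonferroni
comparisons always equals the number of condition pairs present in the
input, so whether an isometric (0 deg/s) condition joins the family is
decided by the data given, not hard-coded.

## The synthetic-data generator

No public grid-EMG recordings accompany the analyses this package targets,
so `simulateRecording()` generates recordings with exact ground truth:

$$x_{ch}(t) = A\, w_{ch}(t)\, f(t)\, s_{ch}(t) + n(t),$$

with $w_{ch}(t)$ an anisotropic Gaussian spatial envelope evaluated at the
channel's grid position while the envelope centre follows configurable
waypoints (linear interpolation), $f(t)$ a trapezoidal effort profile
(also emitted as a 100 Hz torque channel), $s_{ch}$ a unit-RMS band-limited
Gaussian source per channel, and $n$ white noise at the amplifier-like
noise floor.

Defaults and why:

* `fsHz = 1024`, 13 x 5 grid, one missing corner — the recording setup the
  package targets.
* `noiseFloorMv = 0.002` (2 uV RMS) — a typical hardware noise floor.
* `amplitudeMv = 0.2`, `sigmaRows = 3`, `sigmaCols = 1.5` — produce
  map-mean RMS near 0.07 mV and plateau SNR near 100 at the envelope peak,
  the magnitude of voluntary knee-extension surface EMG.
* `bandHz = c(20, 400)` — the source band equals the analysis band so
  filtering is approximately idempotent on synthetic data; a wider band
  exercises the filter instead.
* The band-limited source is synthesised in the frequency domain (white
  Gaussian spectrum with bins outside the band zeroed, renormalised to
  unit RMS), so the band support is exact and the spectral median of the
  default band is analytically 210 Hz.
* `commonDriveFrac` mixes a shared source across channels (default 0) so
  common-mode rejection of the differential derivation is testable.
* Identical seeds give bit-identical recordings.

What the generator does *not* emulate: motor-unit action-potential shapes
and discharge statistics, volume-conductor anisotropy, conduction-velocity
structure (so the synthetic spectrum is flat rather than peaked near
50–100 Hz, and synthetic median frequencies sit near 210 Hz, not the
70–90 Hz of real muscle), electrode-skin impedance drift, and movement
artefact. Passing tests on synthetic data therefore demonstrate that the
pipeline measures the spatial and spectral properties it is pointed at —
not that real recordings satisfy the generator's assumptions.

## Reporting pipeline and problem sizes

`runPipeline()` drives cohort analyses: per-trial feature tables, per-trial
point and trajectory CoG summaries, the method-agreement correlations, the
normality screens and speed-pair t-tests, midpoint activation-map matrices
and trajectory series as TSV, and a run log of parameters and seeds. For
simulated cohorts, subject-level envelope centres (rows 5.5–8.5, columns
2.6–3.4) and amplitudes (0.12–0.3 mV) are drawn once from the base seed so
subjects differ while reruns are byte-identical; numeric output goes
through a fixed 12-significant-digit formatter for the same reason.

The package's own validation runs at desk scale: 2 s trials for feature
and recovery checks (about 20 seeds for CoG recovery, 8 for spectral
averages), a 5 s trial for the drifting-centre trajectory, cohorts of
3–4 subjects by 2–3 speeds for pipeline checks, and 200 replicates of a
14-subject, 3-speed null cohort for the family-wise-error calibration.
These sizes were chosen as the smallest at which the stochastic checks are
stable across seeds.

## Known limitations

* The generator's amplitude model controls per-channel RMS and band
  support exactly but is not a physiological motor-unit simulator; effects
  that depend on discharge timing (e.g. decomposition, coherence) are out
  of scope.
* Differential intensity's per-trial value depends on the stated
  aggregation convention; alternative conventions (e.g. mean of per-pair
  logs) differ by Jensen-gap amounts on heterogeneous maps.
* CoG estimates near grid edges carry truncation bias (see above); the
  package reports what the grid can see rather than extrapolating beyond
  it.
* Torque is resampled to EMG indices by nearest sample only; sub-sample
  onset alignment is unnecessary at 100 Hz torque against 250 ms windows.
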