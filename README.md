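# gridEMG

Spatial analysis of high-density surface EMG (HDsEMG) grid recordings in R.

HDsEMG records one muscle with a 2D electrode grid (by default 13 rows x 5
columns, one corner absent, 64 channels at 1024 Hz) and represents a time
window as an **activation map**: the RMS amplitude of each channel placed
at its grid position, `HM_ij = RMS(sEMG_ij)`. This package is for
researchers in neurophysiology, rehabilitation and prosthetics who want to
quantify *where* and *how uniformly* a muscle is active — for example to
compare contraction speeds, or an amputated limb's residual muscle against
the intact side — without reassembling the analysis chain by hand.

It provides:

* **Containers and I/O** — S4 classes for grid geometry, multichannel
  recordings, activation maps and CoG trajectories; an open interchange
  format (TSV signal matrix + JSON sidecar, optional 100 Hz torque
  channel) with unit conversion to mV.
* **Preprocessing** — zero-phase 20–400 Hz Butterworth filtering,
  monopolar → single-differential derivation along the fiber axis (59
  channels on the default grid), torque- or envelope-based contraction
  segmentation, windowed RMS mapping.
* **Map features** — intensity `I = log10(mean(HM))`, differential
  intensity, modified entropy
  `E = -Σ q_i log2 q_i` with `q_i = HM_i² / Σ HM_k²` (bits; max
  `log2(N)` for a uniform map), CoV (%), mean RMS (mV), and spectral
  median frequency (Hz).
* **Centre of gravity** — the map barycentre
  `CoG = Σ HM_ij (i,j) / Σ HM_ij` as a single point (midpoint,
  peak-intensity or peak-torque reference) and as a **trajectory** over
  the whole contraction with per-axis mean/variance/range summaries, plus
  Pearson agreement between the two estimators.
* **Group statistics** — Shapiro–Wilk screens, pairwise paired t-tests
  with Bonferroni correction across speed conditions, correlation tables.
* **A synthetic grid-EMG generator** with exact ground truth (Gaussian
  spatial envelope with a configurable drift path, trapezoidal effort,
  band-limited sources, hardware-like noise floor), and an end-to-end
  reporting pipeline (`runPipeline()`) plus a thin CLI
  (`inst/scripts/gridemg.R`).

## Worked example

Simulate one isokinetic-style trial, extract the feature set and both CoG
estimates:

```r
library(gridEMG)

cfg <- simulationConfig(durationS = 4, plateauS = 2.5, seed = 42,
                        speedLabel = "90")
sim <- simulateRecording(cfg)
rec <- bandpassFilter(sim$recording)
seg <- segmentContraction(rec, "torque")
seg
#> ContractionSegment: samples 308-3780 (torque-threshold)

round(featureSet(rec, seg), 4)
#>   entropy     cov intensity differential_intensity mean_rms median_frequency
#> 1   5.122 60.0379   -1.1176                -0.9343   0.0763            202.5

maps <- windowedMaps(rec, seg, windowS = 0.25)
round(cogReference(maps, "peak_intensity"), 3)
#>     x     y
#> 7.033 3.007

cogTrajectory(maps)
#> CoGTrajectory: 13 window(s), 0.425-3.425 s
#>   x: mean 7.019, var 0.0003, range 0.059 | y: mean 3.004, var 0.0001, range 0.034
```

Reading the numbers: entropy 5.12 bits against a 5.88-bit maximum and CoV
60% say the simulated source is moderately localised; intensity −1.12 is
`log10` of the 0.076 mV map mean; the median frequency sits at the
midpoint of the generator's flat 20–400 Hz band. Both CoG estimators
recover the configured envelope centre (7, 3) to within a few hundredths
of an electrode: the point estimate from the peak-intensity window and the
trajectory mean agree, and the small trajectory range reflects a
stationary source. (`x` is the row coordinate along the muscle-fiber axis,
`y` the column coordinate; multiply by the 8 mm inter-electrode distance
for mm.)

Cohort-level reports — per-trial feature tables, CoG summaries, method
agreement and speed statistics as TSV — come from a config:

```r
runPipeline(list(simulate = list(subjects = 14, speeds = c(60, 90, 120),
                                 seed = 1)),
            outDir = "report")
```

See the methods vignette (`vignettes/gridemg-methods.Rmd`) for the models,
conventions and their rationale.

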