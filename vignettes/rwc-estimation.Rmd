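---
title: "Estimating leaf water content from resonant ultrasound spectra"
author: "rusleaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf water content from resonant ultrasound spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rusleaf)
```

## The problem

Relative water content,

$$\mathrm{RWC} = \frac{FM - DM}{TM - DM},$$

is the standard ecophysiological measure of how hydrated a leaf is
(1 = fully turgid, 0 = oven-dry). Measuring it classically requires
weighing the same leaf fresh ($FM$), fully rehydrated ($TM$) and
oven-dried ($DM$) — destructive, slow, and impossible to do
instantaneously in the field.

Non-contact resonant ultrasound spectroscopy (NC-RUS) offers a way
around this. A leaf held between air-coupled transducers behaves as a
thin resonant plate: its through-transmission spectrum shows maxima at
the thickness resonances $f_n = n\,c/(2h)$, where $c$ is the sound
speed in the leaf and $h$ its thickness. Both quantities — and the
ultrasonic attenuation — change as the leaf loses water, so the
position, height and width of the first resonance encode the
hydration state. `rusleaf` implements the full analysis chain that
turns calibrated transmission-coefficient spectra into RWC estimates
with two regressors:

* a **1D convolutional network** consuming the whole two-channel
  (magnitude, phase) spectrum, and
* a **random forest** consuming four resonance-derived parameters
  (peak magnitude, peak frequency, peak phase, normalized $-6$ dB
  bandwidth).

Because the bench datasets this kind of study rests on are typically
not public, the package ships a physics-based generator of complete
annotated drying experiments, so every stage is testable end to end.

## The synthetic drying experiment

`simulateDataset()` emulates a bench campaign: 31 mature leaves of one
species, each measured at around nine drying states (the per-leaf
count is drawn from $\{8,9,10\}$ and adjusted so the default campaign
has exactly 280 measurements), with three transducer bands per
measurement (0.15–0.35, 0.35–0.95, 0.5–1.6 MHz; log-uniform native
grids of 81/121/111 points). RWC values follow the hydration coverage
such campaigns report: 63% of measurements above the turgor-loss
point (uniform on $[0.88, 1]$), the rest uniform on $[0.52, 0.88)$,
sorted per leaf in drying order. Fresh masses are back-computed as
$FM = DM + \mathrm{RWC}\,(TM - DM)$, so annotation and masses
round-trip exactly.

### Forward model

Spectra come from the normal-incidence transmission coefficient of a
homogeneous lossy plate in air,

$$T(f) = \left[\cos(kh) + \tfrac{i}{2}\left(z + \tfrac1z\right)
\sin(kh)\right]^{-1},
\qquad z = \frac{\rho c}{Z_\mathrm{air}},$$

with complex wavenumber $k = 2\pi f/c - i\,\alpha(f)$ and attenuation
growing linearly with frequency, $\alpha(f) = \alpha_\mathrm{1MHz}
\cdot f/\mathrm{1\,MHz}$ (the minimal dispersion law that keeps the
resonances finite-Q). The sign of the imaginary part follows the
$e^{-ikx}$ wave convention, under which a matched lossy plate
transmits $|T| = e^{-\alpha h} \le 1$; passivity ($|T|\le 1$ for every
state) is asserted in the tests. A single homogeneous layer is the
simplest model that reproduces the observed phenomenology — a
dominant first thickness resonance that moves down in frequency,
loses height and broadens as the leaf dries; the generator interface
accepts alternative forward models through the same trait/state
plumbing.

### Trait priors and the RWC mapping

Each leaf draws turgid/dry endpoint traits from uniform priors
(`traitPriors()`), and `traitsAtRwc()` interpolates thickness, speed,
density and attenuation linearly in RWC between those endpoints. The
priors encode a single-species population of mature evergreen leaves:
turgid thickness 420–480 µm (shrinking to 75–85% dry), turgid speed
310–350 m/s (dropping to 18–28% dry — loss of turgor softens the
tissue strongly), density 880–960 kg/m³, attenuation 450–650 Np/m at
1 MHz rising 2.5–3.5× on drying, dry mass 0.2–0.5 g with a 2.2–3.2
turgid/dry mass ratio. Two consequences are guaranteed by
construction and verified by property tests:

* $f_1(\mathrm{RWC}) = c/2h$ is **strictly increasing** in RWC for
  every possible draw (the relative speed contrast always exceeds the
  relative thickness contrast), and stays inside the instrument
  window for RWC $\in [0.5, 1]$;
* the within-leaf resonance shift across the measured range
  (roughly 25–35%) exceeds the across-leaf spread at equal hydration,
  which is what makes leaf-held-out prediction possible at all — the
  same property the single-species bench campaigns exhibit.

Measurement noise is additive Gaussian on the calibrated channels
(0.5 dB magnitude, 0.05 rad phase), doubled over the outer 10% of
each band to mimic transducer sensitivity roll-off.

### What the generator does not emulate

Real leaves are layered (palisade/spongy mesophyll), show
species-dependent attenuation dispersion, venation-dependent lateral
structure, and acquisition artifacts (transducer transfer functions,
diffraction, alignment). Passing the package's tests therefore shows
the *analysis chain* is correct and that the benchmark holds under
the stated statistical structure — not that any particular real
dataset will reach the same accuracy.

## Preprocessing conventions

`concatenateBands()` pools the three bands sorted by frequency. Phase
is unwrapped per band and again across the pooled sequence, since
interpolating wrapped phase across $\pm\pi$ (or across a $2\pi$
inter-band offset) is meaningless. Points with *exactly* equal
frequencies — the shared 0.35 MHz edge — are averaged; near-duplicate
points from overlapping bands are retained.

`resampleSpectrum()` interpolates both channels onto the common
601-point grid (100 kHz–1.6 MHz, 2.5 kHz). Seven methods are
implemented, and running all seven (`augmentSpectrum()`) is the ×7
augmentation: 280 measurements become 1960 samples of size
[601 × 2]. Two deliberate disambiguations, since numerical toolkits
offer two distinct cubic families:

* `cubic` = shape-preserving piecewise-cubic Hermite (PCHIP);
* `splines` = the classical cubic spline (endpoint-fitted boundary);
* `akima` = classical Akima slopes evaluated as a cubic Hermite
  spline (implemented in-package; see note below).

Below the lowest measured frequency (100–150 kHz) every method holds
the nearest measured value — extrapolating a spline there would blow
up. The classical spline *does* ring visibly on noisy near-duplicate
points in the band-overlap regions; that is faithful behaviour of
that method, it is one version among seven, and the per-measurement
aggregation (mean over versions) dilutes it.

`.akimaChannel()` exists because the installed `pracma::akimaInterp`
contains an indexing defect that returns `NA` over the final
interpolation interval; the in-package implementation follows the
classical construction and is cross-checked against `pracma` on
interior queries in development.

## Features

`extractFeatures()` computes the four derived parameters on the
resampled grid (so forest and network consume aligned inputs): the
global maximum of the magnitude channel (ties broken toward low
frequency; for sub-wavelength leaves the fundamental dominates, and a
first-local-maximum variant is available behind a flag), the
frequency and phase at that maximum, and the normalized $-6$ dB
bandwidth: linear-interpolated crossings of
$\mathrm{peak} - 6\,\mathrm{dB}$ nearest the peak on each side,
$(f_{hi} - f_{lo})/f_\mathrm{peak}$. The $-6$ dB threshold is applied
on the dB magnitude channel relative to the peak. If no crossing
exists on one side within the grid, the feature is flagged undefined,
and such samples are excluded from forest training and logged. A
brute-force full-grid scan oracle and a closed-form parabola check
guard both operations.

## Cross-validation and balancing

`leafooSplits()` implements leaf-one-out cross-validation: one fold
per leaf; all measurements of a leaf — and all seven interpolated
versions of each — travel together, so a fold's test leaf contributes
nothing to training (leakage is asserted per fold). This mirrors the
deployment scenario: predicting the RWC of a leaf the model has never
seen.

Because near-turgid samples dominate the campaign, each training set
is rebalanced by density-dependent downsampling
(`balanceTrainingSet()`): the training RWC range is cut into 10
equal-width bins (≈0.05 RWC wide over the observed range, matching
the data's granularity), the smallest nonempty bin sets the target,
and every bin is subsampled without replacement to that target —
the strictest reading of "nearly uniform". Discarded samples form a
pseudo-validation pool. Balancing operates on augmented samples, and
is re-drawn independently (fresh derived seed) in every fold.

## The two regressors

### Random forest

`trainRf()` wraps `randomForest`: 400 regression trees on bootstrap
samples drawn with replacement, 2 of the 4 variables considered per
split, at least 3 observations per tree leaf, seeded. The forest
never sees undefined-bandwidth rows.

### The 1D convolutional network

`buildCnn()`/`trainCnn()` implement an 18-layer network in compiled
code (single precision, convolutions as one BLAS gemm per kernel tap
on zero-padded activations): input [601 × 2] →
conv(17 kernels, size 11)+BN+ReLU → conv(55, 7)+BN+ReLU → maxpool(2)
→ conv(70, 11)+BN+ReLU → maxpool(2) → FC(25) → dropout(0.3) → FC(25)
→ dropout(0.3) → FC(1), trained with mean-squared-error loss under
SGDM (minibatch 32, momentum 0.8247, L2 1.25e-7 on weight matrices,
initial learning rate 0.0875 with three factor-10 drops). Choices the
architecture enumeration leaves open, fixed here:

* **Padding/stride**: same-padding, stride 1; pooling window 2 with
  stride 2 after the last two conv blocks.
* **LR schedule**: drops at epochs $\lceil E\,k/4\rceil$,
  $k = 1, 2, 3$ — evenly spaced, the standard piecewise default.
* **Input standardization**: per channel (magnitude, phase) to zero
  mean/unit variance using training-fold statistics only — batch
  norm alone does not normalize the input layer.
* **Initialization**: uniform fan-in for the convolutional stack.
  The fully connected head (which is linear — the enumeration places
  no ReLU between FC layers) uses a 10× smaller scale, and the output
  bias starts at the training-target mean. Both choices keep the
  head's initial gain and the initial residuals small; with a
  10500-input FC layer, the loss curvature along its own gradient
  direction scales with $\|F\|^2$, and the configured large initial
  learning rate is only stable when the head starts small.
* **Batch norm**: population statistics per minibatch,
  $\varepsilon = 10^{-5}$, running estimates with momentum 0.1 used
  at inference; dropout is inverted and disabled at inference.
* **Determinism**: a single seed drives initialization, shuffling
  and dropout; identical seeds give bit-identical weights. Gradients
  are verified against central finite differences (median relative
  error $\sim 10^{-4}$; isolated larger deviations at ReLU/pool kinks
  are a property of finite differences, not of the gradients).

### Evaluation

`buildEvalReport()` reports RMSE, Pearson's $R$ and the least-squares
line of predictions on true RWC, both per augmented sample and per
measurement (mean of the seven interpolated versions — a unique value
per acquired measurement). Per-leaf RMSE feeds a two-sided paired
t-test between model families (`compareModels()`), and
`interpolationAnova()` runs a repeated-measures ANOVA across the
seven methods with Bonferroni and Tukey–Kramer comparisons, the check
that no interpolation method systematically differs.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the full default
campaign: 31 leaves / 280 measurements / 1960 samples, a complete
31-fold forest cross-validation, and the network benchmark at 50
epochs on the first 8 folds — sizes chosen so a complete run stays
comfortable on a single CPU while still exercising every fold
mechanism at the default data scale. The forest benchmark threshold
(per-measurement $R \ge 0.8$, likewise for the reduced network) is a
property of the default generator conditions, not a tuned constant.

## Known limitations

* The forward model is a single homogeneous layer; inversion to leaf
  properties, layered-leaf models and oblique incidence are out of
  scope.
* The network trains in single precision; exact bit-reproducibility
  holds for a fixed BLAS on a fixed platform.
* `aggregateVersions()` weights the interpolated versions equally;
  per-sample metrics weight every version as an independent sample.
* Real-data ingestion expects already-aligned calibration grids
  (`applyCalibration()` refuses mismatched grids rather than
  regridding).
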