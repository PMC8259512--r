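---
title: "Methods: mapping SAN microvasculature to myocyte excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping SAN microvasculature to myocyte excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, estimators and numerical choices behind
`sanmap`, in the spirit of a methods section: what each stage assumes, which
parameters matter, and what the synthetic-data tests do and do not
demonstrate about real data.

## The scientific problem

The sinoatrial node (SAN) is not homogeneous: the superior node (toward the
superior vena cava) is densely vascularized and populated by myocytes that
fire fast, regular action potentials (APs), while the inferior node is
sparsely vascularized and its myocytes fire slowly, irregularly, or produce
only stochastic subthreshold voltage fluctuations. `sanmap` quantifies this
anatomy–function relationship from three kinds of raw data: two-channel 3D
image volumes (HCN4⁺ myocytes / CD31⁺ endothelium), current-clamp membrane
potential recordings at 10 kHz, and confocal line-scan Ca²⁺ kymographs.

## Volumetrics

**Density.** Fractional volume is counted exactly: set voxels over total
voxels per in-plane tile (default 32 × 32 voxels, full depth), with edge
tiles truncated rather than padded, so tile counts always sum to the global
foreground count.

**Distance.** Myocyte-to-vessel proximity uses an exact Euclidean distance
transform (separable lower-envelope algorithm) generalised to anisotropic
voxel spacing, computed in compiled code and checked in the test suite
against a brute-force nearest-vessel search on every instance up to 15³
voxels. Distances are in micrometres; non-myocyte voxels are `NA` rather
than zero so they can never dilute row means.

**Boundary.** The per-row mean distance along the node axis is fitted with a
4-parameter logistic, `d(x) = d_sup + (d_inf − d_sup)/(1 + exp(−k(x −
x₀)))`, by Levenberg–Marquardt least squares (`minpack.lm`). The boundary is
the inflection `x₀` — the only scale-free point of a sigmoid. Starting
values matter more than the optimizer here: the start for `x₀` is the split
point that best separates below-midpoint from above-midpoint rows (robust to
elevated distances at the volume faces, where vessels exist on one side
only), and the best of three seeded starts by residual sum of squares is
kept. A flat profile (range below 0.1% of the median level) is reported as
degenerate with an `NA` boundary instead of a spurious fit. Note one
intrinsic property of this estimator: because the distance field is smooth
across the density step (inferior voxels near the boundary still reach
superior vessels), the half-rise sits a few micrometres inferior to the true
density step, a positive bias of order the inferior plateau distance. On the
default synthetic node this amounts to ~1.5% of node length.

**Skeleton.** Vessel topology comes from sequential 3D thinning: a voxel is
deleted only if it is simple in the (26, 6) sense — one 26-connected object
component in its neighbourhood and one 6-connected background component
touching a face — and not an endpoint, with candidates processed in
ascending distance-to-background order so erosion proceeds from the outside
in. This preserves topology by construction and reduces tubes to
single-voxel curves. The skeleton is traced into segments between junctions
and endpoints; spurs shorter than 3 voxels are pruned; segment length is the
anisotropic polyline length. Known bias: thinning erodes each free tube end
by roughly one tube radius, so skeleton totals slightly underestimate
planted tube lengths (the ground truth therefore records an
overlap-corrected centerline length, and recovery is tested at ±15%).

**Branch orders.** The artery path is order 1; at each junction the child
that best continues the parent's calibre (largest diameter) keeps the
parent's order, other children increment it. This matches how 1°–4° vessels
are traced manually and recovers planted trees exactly when calibres are
ordered, which is the anatomically relevant case (artery ≫ arteriole ≫
capillary). Diameter at a skeleton voxel is twice its distance to
background, averaged along the segment.

## Electrophysiology

**AP detection.** Candidates are upward crossings of the AP threshold
(default −29 mV, the experimentally determined take-off potential) with
2 mV hysteresis — a crossing counts only once the trace has been at least
2 mV below threshold since the last accepted one, which prevents noise
jitter during slow repolarizations from spawning spurious events — plus a
50 ms refractory gap, a minimum phase-0 dV/dt of 1 mV/ms, and a peak above
−20 mV (excluding large subthreshold fluctuations). dV/dt is a central
difference after a 0.5 ms moving average; the 10%-of-maximum rule for the
take-off uses each AP's own maximum, since upstroke velocity varies
cell-to-cell and beat-to-beat.

**Features.** MDP is the most negative potential between APs, localised on
a 2 ms-smoothed copy of the trace (the raw minimum jitters by noise divided
by local slope around the repolarization–diastole junction, which would leak
repolarization samples into the early-diastolic window and bias the EDD rate
low). Diastolic duration runs MDP → take-off; the early diastolic
depolarization (EDD) rate is the least-squares slope over 10–50% of that
interval in mV/s; APD90 is measured from take-off to repolarization through
90% of the take-off-to-peak amplitude. Features needing samples beyond the
trace edge are `NA`, never extrapolated.

**Intervals and modality.** CV is the sample SD over the mean of the
inter-AP intervals. Classification: silent / subthreshold-only by presence
of events; tonic if CV < 0.7; otherwise burst when the upper ISI mode (95th
percentile) exceeds 6 × the median — the signature of silences alternating
with high-frequency clusters, which cleanly separates bursting from
exponential-like irregular firing (whose q95/median ratio is ~3.5) — else
irregular. Both thresholds are arguments, because real recordings show a
continuum.

**Subthreshold events.** The rule is amplitude > baseline mean + 3 SD,
duration ≥ 1 ms at the crossing level, peak below −29 mV. The baseline is
the longest AP-free stretch (≥ 200 ms) summarised by median and MAD — a
robust equivalent of mean/SD chosen because sparse large events would
otherwise inflate the baseline SD and mask small fluctuations. Runs are
found on a 1 ms-smoothed copy and sub-threshold gaps shorter than 3 ms are
merged, so one noisy event is not counted twice.

**Mixtures.** Amplitude histograms are decomposed by a 1D Gaussian-mixture
EM written for this purpose: 10 seeded restarts (quantile start plus
jittered samples), convergence at a relative log-likelihood change below
1e−8, a variance floor of 1e−6 × the data variance against collapse, and
BIC selection between 1 and 2 components. The test suite cross-checks
center recovery against `mclust` as an independent reference and calibrates
the selection layer: on unimodal data, one component wins in ≥ 90% of 50
replicates.

## Ca²⁺ imaging

**Normalization.** ΔF/F₀ = (F − background)/F₀ − 1 with F₀ per spatial
pixel at the 20th percentile of its own time series — low enough to be
insensitive to sparks, high enough to average over noise.

**Spark detection.** Each time line's spatial median is subtracted first:
whole-cell transients span the full line while sparks occupy a small part of
it, so this removes the global Ca²⁺ component and leaves sparks measured
against their local diastolic baseline. The image is then lightly smoothed
(3 × 3 box), thresholded at the robust baseline (median + 3.8 × MAD-SD, the
conventional detection criterion), and connected space–time regions are
split by an intensity watershed with a one-SD tolerance so colliding sparks
are counted separately — without this, detected rate falls ~12% below the
planted rate at 40 events/100 µm·s; with it the rate–rate slope is 0.96.
Components smaller than 4 pixels are rejected; components whose spatial
extent exceeds 60% of the scan line are treated as whole-cell transients.
Amplitude is the peak of the raw (unsmoothed) temporal profile averaged over
the 3 pixels at the spark centre — smoothed peaks underestimate an
instantaneous-rise event, while the raw single-pixel maximum over many
samples is biased high by noise; the 3-pixel average balances the two, and
planted 0.30 ΔF/F₀ sparks are recovered at 0.30 ± 0.01 under 0.03 noise.
FWHM and FDHM are linear interpolations of half-maximum crossings relative
to the local baseline.

## Spark–AP coupling

Sparks are aligned to AP take-offs within a 300 ms pre-AP window (spanning
typical SAN diastolic durations), truncated at the preceding AP. The pre-AP
histogram uses 10 bins normalized to probability per bin; its least-squares
slope against bin index (toward the AP) is the spark-accumulation measure,
in probability · bin⁻² (unit-ambiguous in absolute terms; its sign and
ordering across conditions are the meaningful quantities). Per-spark voltage
deflection is the mean potential 20 ms after the spark peak minus 20 ms
before onset, with AP-overlapping sparks excluded; association is summarized
by Pearson r, r², and adjusted r² (reported because small-sample adjusted
r² can be negative, which bare r² cannot).

## The synthetic generators

The generators exist to give every estimator a ground truth. They emulate
the statistical structure the analyses assume, not microscope physics: no
point-spread function, photobleaching, motion, or cell-shape modelling.

- **Node volumes** (default 32 × 240 × 240 voxels at 1 µm, superior 60% of
  the axis): a primary artery descending the row axis, tapering 14 → 10.7 µm
  (the ~24% taper reported for the SAN artery, scaled to the miniature node
  so the artery does not dominate the cross-section), stratified 2°–4°
  branches, and random capillary segments (2.5–3.5 µm diameter) filled per
  region to the target fractional volumes (defaults 10% superior, 4%
  inferior; myocytes 30%/18%). Capillary centres are sampled in a
  half-length-expanded box and clipped, so coverage is stationary to every
  face; within each region a water-filling rule steers capillaries toward
  rows still below the per-row target, because branch clusters would
  otherwise starve distant rows and tilt the distance profile. The region
  boundary acts as a clipping face, keeping the planted density step crisp.
  These defaults give superior/inferior mean distances of ≈ 3.3/6.3 µm — a
  1.9-fold contrast, matching the reported regional ratio.
- **Voltage traces**: take-off times per modality (tonic: gamma ISIs at CV
  0.05; irregular: 120 ms refractory + exponential tail, so ISI CV
  approaches 1 at low rates while respecting the waveform's refractoriness;
  burst: ~6-AP clusters at 5 Hz between exponential silences), rendered as a
  deterministic waveform — logistic upstroke with the configured maximum
  dV/dt, exponential repolarization tuned to APD90 (asymptote 3 mV below
  MDP so the MDP is reached in finite time), a linear early-diastolic ramp
  at the configured EDD rate over 60% of the diastole with a smooth
  quadratic approach to threshold, and a near-MDP plateau for diastoles
  longer than the configured rate can span. Subthreshold bumps are
  alpha-functions with 5–50 ms durations and mixture-drawn amplitudes,
  placed only where the membrane sits near MDP and always kept below
  −29 mV. Waveform defaults are the regional reference parameters in
  `san_ap_parameters()`. Noise is additive Gaussian at 0.3 mV SD — the
  source recordings' noise level is not reported, so this is a free
  parameter chosen as typical for perforated-patch recordings.
- **Kymographs** (default 50 µm at 0.25 µm/pixel, 4 ms line interval):
  sparks are spatial Gaussians (FWHM 2 µm) with instantaneous rise and
  exponential decay (FDHM 30 ms); transients span the scan line with a
  25 ms linear rise. Amplitudes come from per-region two-component mixtures
  (low population 0.30 ΔF/F₀ in both regions; high 0.9 superior / 1.2
  inferior).
- **Paired recordings** plant Poisson-distributed spark counts per diastole
  with a linearly ramping time density toward the AP (inverse-CDF sampled),
  plus AP-triggered transients.

Passing the recovery suites therefore shows the estimators are unbiased
under the assumed event shapes and stationary Gaussian noise; it does not
certify performance under drift, movement artefacts, photobleaching, or
non-Gaussian noise, which real recordings contain.

## Problem sizes and reproducibility

Every stochastic routine takes a seed, and seeded runs are byte-identical
(the pipeline rerun test compares CSV outputs literally). The test suite
and acceptance script use scaled-down study sizes chosen to exercise each
estimator well past its asymptotic regime: 240-row synthetic nodes (~1.8M
voxels), 20–60 s traces (10⁴ samples/s), 10 s kymographs, 2 000-draw
mixture fits, and 10⁴-interval CV calibrations. Feature-recovery checks on
irregular traces assert detection (recall/precision ≥ 0.98) rather than
waveform-parameter recovery, because a constant configured EDD rate is not
measurable over arbitrarily long diastoles during which the membrane
deliberately rests near MDP — a property of the waveform model, not of the
detector.

## Known limitations

- The boundary estimator's small inferior-ward bias (above) is inherent to
  distance-based boundaries; it is well under the ±5% band used for
  calibration but would grow if the inferior plateau distance approached a
  large fraction of node length.
- Endocardium or other labelled non-vascular structures must be removed
  upstream (an exclusion mask); the package does not attempt it.
- The spark detector is calibrated for line-scan (1D space × time) data
  only, and its amplitude estimator assumes a sub-line-interval rise.
- Branch-order recovery relies on calibre ordering at junctions; trees with
  child branches thicker than their parent will be mis-ordered.
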