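# sanmap

Quantitative mapping of sinoatrial-node (SAN) microvascular anatomy and
pacemaker myocyte excitability, for cardiac physiologists working with
whole-node 3D immunofluorescence volumes (HCN4⁺ myocytes, CD31⁺ endothelium),
single-cell current-clamp recordings, and confocal line-scan Ca²⁺ imaging.

The package implements, as one tested pipeline:

- **3D volumetrics** — fractional-volume density maps
  (`fraction = foreground voxels / total voxels` per tile), an exact
  anisotropic 3D Euclidean distance transform from every myocyte voxel to its
  nearest vessel voxel, and a per-row distance profile along the node axis.
  The superior/inferior boundary is the inflection `x₀` of a 4-parameter
  logistic fitted to that profile by least squares:

  `d(x) = d_sup + (d_inf − d_sup) / (1 + exp(−k (x − x₀)))`

  Vessel topology comes from a 3D curve skeleton (sequential simple-point
  thinning): segments, polyline lengths, 1°–4° branch orders, and per-segment
  diameters (2 × distance from skeleton to background).
- **Electrophysiology** — AP detection at the take-off potential (the point
  where dV/dt first reaches 10% of its phase-0 maximum), per-AP features
  (MDP, diastolic duration, early diastolic depolarization rate as the
  least-squares slope over 10–50% of the diastolic interval, APD90, max
  dV/dt), inter-AP interval statistics (CV = SD/mean, joint-interval pairs),
  tonic/irregular/burst classification, and subthreshold-fluctuation
  detection (amplitude > baseline mean + 3 SD, duration ≥ 1 ms, peak below
  the −29 mV AP threshold).
- **Ca²⁺ imaging** — ΔF/F₀ normalization of line-scan kymographs, a
  criteria-based spark detector (threshold at baseline + 3.8 SD, watershed
  component splitting; amplitude, FWHM, FDHM, rate in events/100 µm·s),
  whole-cell transient quantification, and 1- vs 2-component Gaussian
  mixture decomposition of amplitude histograms (EM, BIC model selection).
- **Spark–AP coupling** — alignment of diastolic sparks to AP take-offs,
  sparks per AP, the slope of the pre-AP spark-probability histogram, and
  per-spark voltage deflections with their amplitude correlation.
- **Synthetic data** — seeded generators for two-channel node volumes,
  voltage traces, kymographs and paired recordings with complete ground
  truth, so every stage is testable without microscope or rig data.

## Worked example

```r
library(sanmap)

nv   <- gen_node_volume(node_volume_config(seed = 1))
myo  <- threshold_mask(nv$volume, "myocyte", "fixed", 0.5)
ves  <- threshold_mask(nv$volume, "vessel",  "fixed", 0.5)
dmap <- distance_transform(myo, ves)
fit  <- fit_region_boundary(distance_profile(dmap))
fit
#> <san_boundary_fit> boundary at row 147.6 (superior fraction 61.5%),
#>   d_sup 3.24 um, d_inf 6.57 um

distance_ecdf(dmap, fit$boundary_row)$summary
#> # A tibble: 2 x 5
#>   region   mean_um median_um       n empty
#>   <chr>      <dbl>     <dbl>   <int> <lgl>
#> 1 superior    3.27      3     336282 FALSE
#> 2 inferior    6.51      6.16  128446 FALSE
```

The fitted inflection sits at ~61% of the node axis (the generator plants the
density step at 60%), and myocytes in the superior region are about half as
far from their nearest vessel as inferior myocytes — the anatomical contrast
the boundary fit is designed to quantify. The same flow applies to recordings:

```r
vt  <- gen_voltage_trace(trace_config(modality = "tonic", region = "superior",
                                      seed = 1))
aps <- detect_aps(vt$trace)
glance(interval_stats(aps$takeoff_time_s))
#> # A tibble: 1 x 5
#>   n_events mean_ms sd_ms     cv frequency_hz
#> 1      120    248.  10.6 0.0427         4.03
```

A detected rate of ~4 Hz with CV ≈ 0.04 recovers the configured tonic
superior-cell train. `run_pipeline(run_config(seed = 1), "out/")` runs the
whole superior-vs-inferior study end to end and writes CSV tables, a JSON
summary and a log.

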