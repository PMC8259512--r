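# shared fixtures (built once per test run) and independent oracles

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

# brute-force nearest-vessel distance, the oracle for the distance transform
brute_force_edt <- function(myocyte, vessel, voxel_size_um) {
  d <- dim(vessel)
  co_v <- which(vessel, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (i in which(myocyte)) {
    idx <- arrayInd(i, d)
    out[i] <- sqrt(min(
      ((co_v[, 1] - idx[1]) * voxel_size_um[1])^2 +
        ((co_v[, 2] - idx[2]) * voxel_size_um[2])^2 +
        ((co_v[, 3] - idx[3]) * voxel_size_um[3])^2
    ))
  }
  out
}

# fraction of planted events matched by a detection within tolerance
match_rate <- function(truth_times, detected_times, tol_s = 0.005) {
  if (length(truth_times) == 0) return(NA_real_)
  hits <- vapply(truth_times, function(t) {
    any(abs(detected_times - t) < tol_s)
  }, logical(1))
  mean(hits)
}

# a solid cylinder along the row axis, for skeleton/diameter tests
make_tube <- function(dims, radius, z0 = NULL, c0 = NULL, rows = NULL) {
  z0 <- z0 %||% ((dims[1] + 1) / 2)
  c0 <- c0 %||% ((dims[3] + 1) / 2)
  rows <- rows %||% seq_len(dims[2])
  m <- array(FALSE, dims)
  disk <- outer((seq_len(dims[1]) - z0)^2, (seq_len(dims[3]) - c0)^2, "+") <= radius^2
  for (j in rows) m[, j, ][disk] <- TRUE
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default-config synthetic node analysed once and reused by several files
node_analysis <- function() {
  fixture("node_default", function() {
    nv <- gen_node_volume(node_volume_config(seed = 101))
    myo <- threshold_mask(nv$volume, "myocyte", "fixed", 0.5)
    ves <- threshold_mask(nv$volume, "vessel", "fixed", 0.5)
    dmap <- distance_transform(myo, ves)
    profile <- distance_profile(dmap)
    boundary <- fit_region_boundary(profile)
    list(nv = nv, myo = myo, ves = ves, dmap = dmap, profile = profile,
         boundary = boundary)
  })
}

# one tonic superior trace, analysed once
tonic_analysis <- function() {
  fixture("tonic_superior", function() {
    cfg <- trace_config(duration_s = 30, modality = "tonic",
                        region = "superior", seed = 202)
    vt <- gen_voltage_trace(cfg)
    aps <- detect_aps(vt$trace)
    feats <- ap_features(vt$trace, aps)
    list(cfg = cfg, vt = vt, aps = aps, feats = feats)
  })
}
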