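test_that("node volume generator realizes density targets and is deterministic", {
  fx <- node_analysis()
  truth <- fx$nv$truth
  cfg <- node_volume_config(seed = 101)
  expect_lt(abs(truth$vessel_density["superior"] - cfg$vessel_density_superior),
            0.10 * cfg$vessel_density_superior)
  expect_lt(abs(truth$vessel_density["inferior"] - cfg$vessel_density_inferior),
            0.10 * cfg$vessel_density_inferior)
  expect_lt(abs(truth$myocyte_density["superior"] - cfg$myocyte_density_superior),
            0.10 * cfg$myocyte_density_superior)
  expect_lt(abs(truth$myocyte_density["inferior"] - cfg$myocyte_density_inferior),
            0.10 * cfg$myocyte_density_inferior)
  # determinism: same config + seed => identical volumes
  small <- node_volume_config(shape = c(16, 60, 60), artery_diameter_superior_um = 5,
                              artery_diameter_inferior_um = 4,
                              branch_counts = c(0, 0, 0), seed = 7)
  a <- gen_node_volume(small)
  b <- gen_node_volume(small)
  expect_identical(a$volume$vessel, b$volume$vessel)
  expect_identical(a$volume$myocyte, b$volume$myocyte)
  expect_identical(a$truth$segments, b$truth$segments)
})

test_that("node volume ground truth is complete and within bounds", {
  fx <- node_analysis()
  segs <- fx$nv$truth$segments
  box <- node_volume_config()$shape * node_volume_config()$voxel_size_um
  expect_true(all(pmin(segs$row0, segs$row1) >= -1e-9 &
                    pmax(segs$row0, segs$row1) <= box[2] + 1e-9))
  expect_true(all(pmin(segs$z0, segs$z1) >= -1e-9 &
                    pmax(segs$z0, segs$z1) <= box[1] + 1e-9))
  expect_true(all(segs$length_um > 0))
  expect_true(all(segs$order %in% 1:4))
  # boundary row matches the configured fraction
  expect_equal(fx$nv$truth$boundary_row, floor(0.6 * 240) + 1)
})

test_that("artery-only configuration plants exactly one segment", {
  cfg <- node_volume_config(
    shape = c(16, 60, 48), vessel_density_superior = NULL,
    vessel_density_inferior = NULL, branch_counts = c(0, 0, 0),
    artery_diameter_superior_um = 8, artery_diameter_inferior_um = 6, seed = 3
  )
  nv <- gen_node_volume(cfg)
  expect_identical(nrow(nv$truth$segments), 1L)
  expect_identical(nv$truth$segments$type, "artery")
})

test_that("infeasible vessel density raises an explicit error", {
  cfg <- node_volume_config(
    shape = c(12, 60, 24), vessel_density_superior = 0.02,
    vessel_density_inferior = 0.02,
    artery_diameter_superior_um = 10, artery_diameter_inferior_um = 9, seed = 1
  )
  expect_error(gen_node_volume(cfg), "infeasible")
})

test_that("tonic trace generator plants the configured AP rate", {
  cfg <- trace_config(duration_s = 60, modality = "tonic", region = "superior",
                      seed = 5)
  vt <- gen_voltage_trace(cfg)
  # 4.04 Hz x ~59.4 usable seconds of a low-jitter train
  expect_equal(length(vt$truth$ap_times_s), 4.04 * 60, tolerance = 0.05)
  # determinism
  vt2 <- gen_voltage_trace(cfg)
  expect_identical(vt$trace$mv, vt2$trace$mv)
  expect_identical(vt$truth$ap_times_s, vt2$truth$ap_times_s)
})

test_that("silent traces carry no APs and no bumps", {
  vt <- gen_voltage_trace(trace_config(duration_s = 5, modality = "silent",
                                       seed = 2))
  expect_length(vt$truth$ap_times_s, 0)
  expect_identical(nrow(vt$truth$subthreshold), 0L)
  expect_lt(diff(range(vt$trace$mv)), 4)  # flat apart from noise
})

test_that("irregular firing has memoryless intervals (CV near 1) at low rates", {
  # slow firing makes the refractory correction negligible, so the planted
  # ISIs are essentially exponential
  cfg <- trace_config(duration_s = 1300, modality = "irregular",
                      ap_frequency_hz = 0.5, region = "superior", seed = 8)
  vt <- gen_voltage_trace(cfg)
  isis <- diff(vt$truth$ap_times_s)
  expect_gte(length(isis), 500)
  expect_lt(abs(sd(isis) / mean(isis) - 1), 0.1)
})

test_that("subthreshold bumps stay below the AP threshold and in bounds", {
  cfg <- trace_config(duration_s = 30, modality = "subthreshold_only",
                      subthreshold_rate_hz = 3, seed = 4)
  vt <- gen_voltage_trace(cfg)
  tr <- vt$truth$subthreshold
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$time_s >= 0 & tr$time_s <= 30))
  expect_true(all(cfg$mdp_mv + tr$amplitude_mv < -29))
  expect_true(all(tr$duration_ms >= 5 & tr$duration_ms <= 50))
})

test_that("kymograph generator plants Poisson spark counts and is deterministic", {
  # expected count = rate x (scan/100) x duration = 3 x 0.5 x 4 = 6
  counts <- vapply(1:40, function(s) {
    cfg <- kymo_config(scan_length_um = 50, duration_s = 4,
                       spark_rate_per_100um_s = 3, seed = s)
    nrow(gen_kymograph(cfg)$truth$sparks)
  }, numeric(1))
  expect_equal(mean(counts), 6, tolerance = 0.25)
  cfg <- kymo_config(duration_s = 2, seed = 9)
  expect_identical(gen_kymograph(cfg)$kymo$fluor, gen_kymograph(cfg)$kymo$fluor)
})

test_that("zero-rate kymograph is flat baseline plus noise", {
  cfg <- kymo_config(duration_s = 2, spark_rate_per_100um_s = 0,
                     transient_frequency_hz = 0, noise_sd_dff = 0.02, seed = 1)
  kg <- gen_kymograph(cfg)
  expect_identical(nrow(kg$truth$sparks), 0L)
  expect_equal(mean(kg$kymo$fluor), cfg$f0_baseline, tolerance = 0.5)
  expect_equal(sd(kg$kymo$fluor), 0.02 * cfg$f0_baseline, tolerance = 0.1)
})

test_that("transient trains are planted at the configured frequency", {
  cfg <- kymo_config(duration_s = 10, spark_rate_per_100um_s = 0,
                     transient_frequency_hz = 4.17, seed = 2)
  kg <- gen_kymograph(cfg)
  expect_equal(nrow(kg$truth$transients), 4.17 * 10, tolerance = 0.05)
})

test_that("oversized spark FWHM is rejected", {
  expect_error(kymo_config(scan_length_um = 10, spark_fwhm_um = 12),
               "FWHM")
})

test_that("paired generator couples the configured spark count to each AP", {
  counts <- c()
  for (s in 1:6) {
    tc <- trace_config(duration_s = 10, modality = "tonic", region = "superior")
    kc <- kymo_config(duration_s = 10, spark_rate_per_100um_s = 0)
    pr <- gen_paired_recording(tc, kc, sparks_per_ap = 4.5, pre_ap_ramp = 1,
                               seed = s)
    coupled <- pr$truth$sparks[!is.na(pr$truth$sparks$ap_id), ]
    counts <- c(counts, nrow(coupled) / length(pr$truth$ap_times_s))
  }
  expect_equal(mean(counts), 4.5, tolerance = 0.1)
})

test_that("zero coupling and mismatched durations behave as specified", {
  tc <- trace_config(duration_s = 5, modality = "tonic", region = "superior")
  kc <- kymo_config(duration_s = 5, spark_rate_per_100um_s = 0)
  pr <- gen_paired_recording(tc, kc, sparks_per_ap = 0, seed = 1)
  expect_identical(nrow(pr$truth$sparks), 0L)
  kc2 <- kymo_config(duration_s = 4)
  expect_error(gen_paired_recording(tc, kc2, seed = 1), "duration")
})

test_that("zero pre-AP ramp gives uniform spark times across the window", {
  # pool relative positions across seeds; under a uniform density the mean
  # of u (0 = window start, 1 = AP) is 1/2
  u <- c()
  for (s in 1:5) {
    tc <- trace_config(duration_s = 10, modality = "tonic", region = "superior")
    kc <- kymo_config(duration_s = 10, spark_rate_per_100um_s = 0)
    pr <- gen_paired_recording(tc, kc, sparks_per_ap = 6, pre_ap_ramp = 0,
                               window_ms = 120, seed = s)
    sp <- pr$truth$sparks
    sp <- sp[!is.na(sp$ap_id), ]
    ap_t <- pr$truth$ap_times_s[sp$ap_id]
    u <- c(u, 1 + (sp$time_s - ap_t) * 1000 / 120)
  }
  expect_gt(length(u), 300)
  expect_equal(mean(u), 0.5, tolerance = 0.05)
})
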