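test_that("no APs are reported on a flat trace and short traces error", {
  tr <- san_trace(rep(-60, 20000) + rnorm(20000, sd = 0.3), 10000)
  expect_identical(nrow(detect_aps(tr)), 0L)
  expect_error(detect_aps(san_trace(rep(-60, 1000), 10000)), "0.5 s")
})

test_that("tonic AP detection matches the planted train", {
  cfg <- trace_config(duration_s = 60, modality = "tonic", region = "superior",
                      seed = 31)
  vt <- gen_voltage_trace(cfg)
  aps <- detect_aps(vt$trace)
  expect_lte(abs(nrow(aps) - length(vt$truth$ap_times_s)), 2)
  expect_gte(match_rate(vt$truth$ap_times_s, aps$takeoff_time_s), 0.98)
})

test_that("take-off lands at the 10%-of-max-slope point of a known upstroke", {
  # piecewise-linear upstroke: 0.8 mV/ms for 5 ms, then 3, then 20 mV/ms.
  # max slope 20 -> 10% = 2 mV/ms, first reached at the 3 mV/ms segment.
  fs <- 10000
  v <- rep(-60, fs)
  t0 <- 5000
  seg1 <- seq(0, by = 0.8 / 10, length.out = 50)                   # 5 ms @0.8
  seg2 <- seg1[50] + seq(0.3, by = 3 / 10, length.out = 50)        # 5 ms @3
  seg3 <- seg2[50] + seq(2, by = 20 / 10, length.out = 38)         # -> +19 mV
  up <- -60 + c(seg1, seg2, seg3)
  dn <- seq(up[length(up)], -61, by = -0.2)
  v[t0 + seq_along(c(up, dn))] <- c(up, dn)
  tr <- san_trace(v, fs)
  aps <- detect_aps(tr)
  expect_identical(nrow(aps), 1L)
  expected_takeoff <- (t0 + 50) / fs   # start of the 3 mV/ms segment
  expect_lt(abs(aps$takeoff_time_s - expected_takeoff), 0.001)
  expect_lt(abs(aps$takeoff_mv - (-56)), 1.5)
  expect_lt(abs(aps$max_dvdt_mv_ms - 20), 2)
})

test_that("take-off detection is invariant to offset and time shift", {
  cfg <- trace_config(duration_s = 10, modality = "tonic", region = "superior",
                      seed = 6)
  vt <- gen_voltage_trace(cfg)
  aps <- detect_aps(vt$trace)
  shifted <- san_trace(vt$trace$mv + 7, 10000)
  aps2 <- detect_aps(shifted, ap_threshold_mv = -29 + 7)
  expect_equal(aps2$takeoff_time_s, aps$takeoff_time_s, tolerance = 1e-8)
  lagged <- san_trace(c(rep(vt$trace$mv[1], 10000), vt$trace$mv), 10000)
  aps3 <- detect_aps(lagged)
  expect_equal(aps3$takeoff_time_s, aps$takeoff_time_s + 1, tolerance = 2e-4)
})

test_that("a pure linear diastolic ramp yields its slope as the EDD rate", {
  fs <- 10000
  ap <- function() c(seq(-40, 20, by = 2), seq(19.5, -60.25, by = -0.5))
  ramp <- -60 + 0.05 * (0:5999) / 10    # 50 mV/s for 600 ms
  v <- c(rep(-60, 3000), ap(), ramp, seq(-30 + 2, 20, by = 2),
         seq(19.5, -60, by = -0.5), rep(-60, 3000))
  feats <- ap_features(san_trace(v, fs))
  expect_identical(nrow(feats), 2L)
  expect_lt(abs(feats$edd_rate_mv_s[2] - 50), 0.5)
})

test_that("APD90 of a triangular AP matches the closed form", {
  fs <- 10000
  a <- 2                      # mV per sample = 20 mV/ms
  peak <- 20; base <- -60
  rise <- seq(base, peak, by = a)
  fall <- seq(peak - a, base, by = -a)
  v <- c(rep(base, 6000), rise, fall, rep(base, 6000))
  feats <- ap_features(san_trace(v, fs))
  expect_identical(nrow(feats), 1L)
  # take-off ~ base; APD90 = (1 + 0.9) * (peak - takeoff) / slope
  expected <- 1.9 * (peak - feats$takeoff_mv) / 20
  expect_lt(abs(feats$apd90_ms - expected), 1)
})

test_that("waveform features of tonic traces recover the generator parameters", {
  # bump-free traces isolate the AP waveform itself
  for (rg in c("superior", "inferior")) {
    cfg <- trace_config(duration_s = 30, modality = "tonic", region = rg,
                        subthreshold_rate_hz = 0, seed = 17)
    vt <- gen_voltage_trace(cfg)
    f <- ap_features(vt$trace)
    expect_lt(abs(mean(f$edd_rate_mv_s, na.rm = TRUE) / cfg$edd_rate_mv_s - 1), 0.10)
    expect_lt(abs(mean(f$mdp_mv, na.rm = TRUE) / cfg$mdp_mv - 1), 0.10)
    expect_lt(abs(mean(f$apd90_ms, na.rm = TRUE) / cfg$apd90_ms - 1), 0.10)
    expect_lt(abs(mean(f$max_dvdt_mv_ms, na.rm = TRUE) / cfg$dvdt_max_mv_ms - 1), 0.10)
    expect_lt(abs(mean(f$takeoff_mv, na.rm = TRUE) - cfg$takeoff_mv), 2)
  }
})

test_that("interval statistics match hand arithmetic and closed forms", {
  st <- interval_stats(c(0, 0.1, 0.3, 0.6))   # ISIs 100, 200, 300 ms
  expect_equal(st$mean_ms, 200)
  expect_equal(st$sd_ms, 100)
  expect_equal(st$cv, 0.5)
  expect_equal(st$frequency_hz, 3 / 0.6)
  # perfectly periodic => CV 0
  stp <- interval_stats(seq(0, 10, by = 0.25))
  expect_equal(stp$cv, 0)
  # joint pairs conserve count: #pairs = #ISIs - 1
  expect_identical(nrow(st$joint), length(st$intervals_ms) - 1L)
  expect_identical(nrow(stp$joint), length(stp$intervals_ms) - 1L)
  # exponential ISIs at n = 10000 => CV = 1 +- 0.03
  set.seed(13)
  ste <- interval_stats(cumsum(rexp(10001, rate = 4)))
  expect_lt(abs(ste$cv - 1), 0.03)
  # fewer than 2 events: frequency flagged
  st1 <- interval_stats(1.5)
  expect_true(st1$frequency_flagged)
  expect_true(is.na(st1$frequency_hz))
})

test_that("firing modalities are recovered from generated traces", {
  labels <- c(tonic = "tonic", irregular = "irregular", burst = "burst")
  for (mod in names(labels)) {
    rg <- if (mod == "tonic") "superior" else "inferior"
    cfg <- trace_config(duration_s = 40, modality = mod, region = rg, seed = 23)
    vt <- gen_voltage_trace(cfg)
    aps <- detect_aps(vt$trace)
    subs <- detect_subthreshold(vt$trace, aps)
    expect_identical(classify_modality(aps, subs), unname(labels[mod]),
                     label = mod)
  }
  expect_identical(classify_modality(NULL, NULL), "silent")
  empty_aps <- detect_aps(san_trace(rep(-60, 10000) + rnorm(10000, sd = 0.1), 10000))
  bumps <- tibble::tibble(event_id = 1:3)
  expect_identical(classify_modality(empty_aps, bumps), "subthreshold_only")
})

test_that("the 3-SD / 1-ms rule has a near-zero false-positive rate on noise", {
  set.seed(29)
  tr <- san_trace(-60 + rnorm(600000, sd = 0.5), 10000)
  subs <- detect_subthreshold(tr)
  expect_lt(nrow(subs) / 60, 0.1)   # Hz
})

test_that("planted subthreshold bumps are recovered and AP-sized ones rejected", {
  cfg <- trace_config(duration_s = 60, modality = "subthreshold_only",
                      subthreshold_amp_mixture = list(c(1, 5, 0.5)),
                      noise_sd_mv = 0.5, mdp_mv = -60, takeoff_mv = -36,
                      seed = 5)
  vt <- gen_voltage_trace(cfg)
  subs <- detect_subthreshold(vt$trace)
  expect_gte(match_rate(vt$truth$subthreshold$peak_time_s, subs$peak_time_s,
                        tol_s = 0.02), 0.95)
  expect_true(all(subs$duration_ms >= 1))
  expect_true(all(subs$peak_abs_mv < -29))
  # a bump peaking at -24 mV exceeds the take-off threshold and is rejected
  v <- c(rep(-60, 5000), -60 + 36 * exp(-abs(seq(-500, 500)) / 80),
         rep(-60, 5000)) + rnorm(11001, sd = 0.2)
  expect_identical(nrow(detect_subthreshold(san_trace(v, 10000))), 0L)
})

test_that("amplitude mixtures recover printed superior and inferior components", {
  set.seed(7)
  x <- sanmap:::sample_mixture(2000, list(c(0.5, 2.0, 1.3), c(0.5, 11.0, 1.1)))
  fit <- fit_amplitude_mixture(x)
  expect_identical(fit$k, 2L)
  expect_lt(abs(fit$centers[1] - 2.0), 0.2)
  expect_lt(abs(fit$centers[2] - 11.0), 0.3)
  set.seed(8)
  y <- rnorm(2000, 6, 2.3)
  fit1 <- fit_amplitude_mixture(y)
  expect_identical(fit1$k, 1L)
  expect_lt(abs(fit1$centers - 6), 0.2)
  # degenerate data and the n >= 30 precondition
  expect_true(fit_amplitude_mixture(rep(3, 100))$degenerate)
  expect_error(fit_amplitude_mixture(rnorm(10)), "30")
})

test_that("condition comparison recovers a planted depolarization", {
  set.seed(19)
  before <- tibble::tibble(
    cell = paste0("c", 1:8),
    resting_potential_mv = rnorm(8, -60, 2),
    event_frequency_hz = rnorm(8, 2.1, 0.4)
  )
  after <- before
  after$resting_potential_mv <- before$resting_potential_mv + 20 + rnorm(8, 0, 0.5)
  cc <- compare_conditions(before, after)
  rp <- cc$tests[cc$tests$metric == "resting_potential_mv", ]
  expect_lt(abs(rp$mean_delta - 20), 1)
  expect_lt(rp$p_value, 0.001)
  ef <- cc$tests[cc$tests$metric == "event_frequency_hz", ]
  expect_equal(ef$mean_delta, 0)
  # identical inputs: all deltas zero
  cc0 <- compare_conditions(before, before)
  expect_true(all(unlist(cc0$deltas[-1]) == 0))
  expect_error(compare_conditions(before, after[1:5, ]), "paired")
})
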